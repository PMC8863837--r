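JOINTS <- c("ankle", "knee", "hip")
PLANES <- c("sagittal", "frontal", "transverse")
MODALITIES <- c("angle", "moment")

#' Canonical trajectory names
#'
#' The 18 trajectories of a trial are the joint angles and joint moments of
#' the ankle, knee and hip in the sagittal, frontal and transverse planes.
#' The canonical order is modality-major (all angles before all moments, so
#' kinematic features precede kinetic features in a combined matrix), then
#' joint (ankle, knee, hip), then plane (sagittal, frontal, transverse).
#' A trajectory name is rendered `"<joint>_<plane>_<modality>"`.
#'
#' @param modality optionally restrict to `"angle"` (kinematics) or
#'   `"moment"` (kinetics).
#' @return Character vector of trajectory names in canonical order.
#' @examples
#' trajectory_names()          # 18 names
#' trajectory_names("angle")   # the 9 kinematic trajectories
#' @export
trajectory_names <- function(modality = NULL) {
  mods <- if (is.null(modality)) MODALITIES else match.arg(modality, MODALITIES)
  out <- character(0)
  for (m in mods)
    for (j in JOINTS)
      for (p in PLANES)
        out <- c(out, paste(j, p, m, sep = "_"))
  out
}

#' Parse a trajectory name into its (joint, plane, modality) triple
#'
#' @param name character vector of trajectory names such as
#'   `"knee_transverse_angle"`.
#' @return A data.frame with columns `name`, `joint`, `plane`, `modality`.
#' @export
parse_trajectory <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("not a trajectory name: ", paste(name[bad], collapse = ", "))
  joint <- vapply(parts, `[[`, "", 1L)
  plane <- vapply(parts, `[[`, "", 2L)
  modality <- vapply(parts, `[[`, "", 3L)
  if (!all(joint %in% JOINTS) || !all(plane %in% PLANES) ||
      !all(modality %in% MODALITIES))
    stop("not a trajectory name: ",
         paste(name[!(joint %in% JOINTS & plane %in% PLANES &
                        modality %in% MODALITIES)], collapse = ", "))
  data.frame(name = name, joint = joint, plane = plane, modality = modality,
             stringsAsFactors = FALSE)
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
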