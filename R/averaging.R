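#' Cohort of sampled skulls sharing one direction set
#'
#' Because every member is resampled on the identical hemi-icosphere, the
#' per-ray radii are directly comparable and averageable.
#'
#' @param members list of [sampled_surface()] objects.
#' @param age_group_label free-text label, e.g. `"11-14 months"`.
#' @return An object of class `sampled_cohort`.
#' @export
sampled_cohort <- function(members, age_group_label = "") {
  if (length(members) < 1L)
    cs_abort("cohort needs at least one member", "cranioshape_input_error")
  ref <- members[[1]]$sampling
  for (m in members) {
    s <- m$sampling
    if (s$subdivision_level != ref$subdivision_level ||
        nrow(s$directions) != nrow(ref$directions) ||
        max(abs(s$origin - ref$origin)) > 1e-12 ||
        max(abs(s$directions - ref$directions)) > 1e-12)
      cs_abort("cohort members use different samplings",
               "cranioshape_input_error")
  }
  structure(list(members = members, age_group_label = age_group_label),
            class = "sampled_cohort")
}

#' Average sampled skulls into a reference skull
#'
#' Per direction, the inner and outer radii are the arithmetic means over
#' the cohort members (averaging the intersection coordinate along a
#' shared ray is the same as averaging its radius), optionally multiplied
#' by an overcorrection scale. Members must be hole-filled first (see
#' [fill_missing()]); a surgeon-specific overcorrection anticipating
#' postoperative growth is applied by `overcorrection_scale > 1`.
#'
#' @param cohort a [sampled_cohort()] of fully valid members.
#' @param overcorrection_scale positive scalar (default 1, no
#'   overcorrection).
#' @return a fully valid [sampled_surface()].
#' @export
average_sampled <- function(cohort, overcorrection_scale = 1.0) {
  if (!inherits(cohort, "sampled_cohort"))
    cs_abort("cohort must be a sampled_cohort", "cranioshape_input_error")
  if (!is.finite(overcorrection_scale) || overcorrection_scale <= 0)
    cs_abort("overcorrection scale must be positive", "cranioshape_input_error")
  for (m in cohort$members)
    if (!all(m$valid))
      cs_abort("cohort members must be hole-filled before averaging",
               "cranioshape_precondition_error")
  inner <- rowMeans(vapply(cohort$members, function(m) m$inner,
                           numeric(length(cohort$members[[1]]$inner))))
  outer <- rowMeans(vapply(cohort$members, function(m) m$outer,
                           numeric(length(cohort$members[[1]]$outer))))
  sampled_surface(cohort$members[[1]]$sampling,
                  inner * overcorrection_scale,
                  outer * overcorrection_scale,
                  rep(TRUE, length(inner)))
}

#' Reconstruct a layer mesh from a sampled surface
#'
#' Vertices are `origin + radius * direction` for the chosen layer; faces
#' are the sampling faces, so vertex/face numbering is identical across
#' all skulls sampled on the same hemi-icosphere.
#'
#' @param sampled a fully valid [sampled_surface()].
#' @param layer `"outer"` (default; the layer used for shape comparison)
#'   or `"inner"`.
#' @return a [triangle_mesh()].
#' @export
sampled_to_mesh <- function(sampled, layer = c("outer", "inner")) {
  layer <- match.arg(layer)
  if (!all(sampled$valid))
    cs_abort("sampled surface has invalid entries; fill holes first",
             "cranioshape_precondition_error")
  r <- if (layer == "outer") sampled$outer else sampled$inner
  V <- sweep(sampled$sampling$directions * r, 2, sampled$sampling$origin, "+")
  triangle_mesh(V, sampled$sampling$faces, validate = FALSE)
}
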