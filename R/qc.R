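#' Quality-control policy
#'
#' Fixes which per-pixel quality codes survive masking and which scenes are
#' eligible at all. Defaults: mandatory-QA codes 0 (good) and 1 (other
#' quality, usable) are accepted, per common thermal-product practice;
#' scene-classification classes for cloud shadow (3), cloud medium/high
#' probability (8, 9), thin cirrus (10) and the no-data/saturated classes
#' (0, 1) are rejected; scenes at or above 80 % cloud cover are ineligible
#' (strictly-lower-than comparison).
#'
#' @param accepted_mandatory_qa Accepted 2-bit mandatory-QA codes.
#' @param rejected_scl_classes Scene-classification classes masked out.
#' @param cloud_cover_max_pct Eligibility ceiling in percent, `[0, 100]`.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(accepted_mandatory_qa = c(0L, 1L),
                      rejected_scl_classes = c(0L, 1L, 3L, 8L, 9L, 10L),
                      cloud_cover_max_pct = 80) {
  if (!length(accepted_mandatory_qa))
    stop("accepted mandatory-QA set must be non-empty", call. = FALSE)
  if (cloud_cover_max_pct < 0 || cloud_cover_max_pct > 100)
    stop("`cloud_cover_max_pct` must be in [0, 100]", call. = FALSE)
  structure(list(accepted_mandatory_qa = as.integer(accepted_mandatory_qa),
                 rejected_scl_classes = as.integer(rejected_scl_classes),
                 cloud_cover_max_pct = as.numeric(cloud_cover_max_pct)),
            class = "qc_policy")
}

#' Decode a quality-control byte
#'
#' Splits an 8-bit QC value into its mandatory-QA field (bits 0-1) and
#' data-quality field (bits 2-3). The remaining bits (emissivity/LST error
#' classes) are returned raw and not acted on by the default policy.
#'
#' @param qc_value Integer vector in `[0, 255]`.
#' @return Data frame with `mandatory_qa`, `data_quality`, `remaining_bits`.
#' @examples
#' decode_qc_bits(c(0L, 2L, 13L))
#' @export
decode_qc_bits <- function(qc_value) {
  qc_value <- as.integer(qc_value)
  if (anyNA(qc_value) || any(qc_value < 0L | qc_value > 255L))
    stop("QC values must be integers in [0, 255]", call. = FALSE)
  data.frame(mandatory_qa = qc_value %% 4L,
             data_quality = (qc_value %/% 4L) %% 4L,
             remaining_bits = qc_value %/% 16L)
}

#' Mask a layer with its quality-control band
#'
#' Cells whose mandatory-QA code is not in the accepted set become nodata;
#' retained cells are bitwise-unchanged.
#'
#' @param layer Science [raster_layer()].
#' @param qc_layer QC [raster_layer()] on the same grid (byte codes).
#' @param policy A [qc_policy()].
#' @return The masked [raster_layer()].
#' @export
apply_qc_mask <- function(layer, qc_layer, policy = qc_policy()) {
  if (!grids_identical(layer$grid, qc_layer$grid))
    stop("layer and QC band are on different grids", call. = FALSE)
  qa <- qc_layer$values %% 4L
  v <- layer$values
  v[is.na(qc_layer$values) | !(qa %in% policy$accepted_mandatory_qa)] <- NA_real_
  raster_layer(layer$grid, v, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

#' Mask a layer with a scene-classification band
#'
#' Cells whose scene-classification class is in the rejected set (clouds,
#' cloud shadow, cirrus, no-data classes by default) become nodata.
#'
#' @param layer Science [raster_layer()].
#' @param scl_layer Class [raster_layer()] on the same grid.
#' @param policy A [qc_policy()].
#' @return The masked [raster_layer()].
#' @export
apply_scl_mask <- function(layer, scl_layer, policy = qc_policy()) {
  if (!grids_identical(layer$grid, scl_layer$grid))
    stop("layer and scene-classification band are on different grids",
         call. = FALSE)
  v <- layer$values
  bad <- is.na(scl_layer$values) |
    (scl_layer$values %in% policy$rejected_scl_classes)
  v[bad] <- NA_real_
  raster_layer(layer$grid, v, layer$variable, layer$level, layer$timestamp,
               layer$overpass)
}

#' Scene eligibility by cloud cover
#'
#' A scene is eligible when its reported cloud-cover percentage is strictly
#' lower than the policy ceiling.
#'
#' @param cloud_cover_pct Scene cloud cover in percent.
#' @param policy A [qc_policy()].
#' @return Logical vector.
#' @examples
#' scene_eligible(c(0, 79.9, 80, 100))
#' @export
scene_eligible <- function(cloud_cover_pct, policy = qc_policy()) {
  if (any(cloud_cover_pct < 0 | cloud_cover_pct > 100, na.rm = TRUE))
    stop("cloud cover must be in [0, 100]", call. = FALSE)
  cloud_cover_pct < policy$cloud_cover_max_pct
}
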