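#' Proliferation index from per-cell marker calls
#'
#' Computes the percentage of denominator-marker-positive cells that are
#' also positive for every numerator marker, e.g. EdU+ among DAPI+
#' (monoculture), EdU+ among HNA+ (co-culture) or EdU+ among GFP+
#' (allografts). Three aggregations are reported, and they answer
#' different questions:
#' \itemize{
#'   \item per field: the index within each imaging field;
#'   \item pooled: total numerator over total denominator across all
#'     fields, i.e. cell-weighted (what a single large field would give);
#'   \item field mean: the unweighted mean of per-field indices (what
#'     averaging the systematically sampled center/margin fields gives).
#' }
#' Group-level values (per animal, well, or coverslip) are unweighted
#' means of pooled per-group indices.
#'
#' @param table `data.frame` with one row per cell: logical marker
#'   columns plus `field_id` and optionally `group_id`.
#' @param numerator character vector of marker column names that must all
#'   be positive (e.g. `"EdU"`).
#' @param denominator single marker column defining the counted
#'   population (e.g. `"DAPI"`, `"HNA"`, `"GFP"`).
#' @return list with `per_field` (data.frame: field_id, n_num, n_den,
#'   index), `pooled` (percent), `field_mean` (percent), and `per_group`
#'   (data.frame, when `group_id` present).
#' @export
proliferation_index <- function(table, numerator, denominator) {
  assert_that(is.data.frame(table), "table must be a data.frame")
  assert_that(all(c(numerator, denominator, "field_id") %in% names(table)),
              "table must contain field_id plus all marker columns")
  num_pos <- Reduce(`&`, lapply(numerator, function(mk) as.logical(table[[mk]])))
  den_pos <- as.logical(table[[denominator]])
  fields <- unique(table$field_id)
  per_field <- do.call(rbind, lapply(fields, function(f) {
    sel <- table$field_id == f
    n_den <- sum(den_pos[sel])
    n_num <- sum(num_pos[sel] & den_pos[sel])
    data.frame(field_id = f, n_num = n_num, n_den = n_den,
               index = if (n_den > 0) 100 * n_num / n_den else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(per_field$n_den == 0)) {
    warning("excluding field(s) with zero denominator cells: ",
            paste(per_field$field_id[per_field$n_den == 0], collapse = ", "))
  }
  keep <- per_field$n_den > 0
  if (!any(keep)) abort("all fields have zero denominator cells")
  pooled <- 100 * sum(per_field$n_num[keep]) / sum(per_field$n_den[keep])
  field_mean <- mean(per_field$index[keep])
  per_group <- NULL
  if ("group_id" %in% names(table)) {
    groups <- unique(table$group_id)
    per_group <- do.call(rbind, lapply(groups, function(g) {
      sel <- table$group_id == g & den_pos
      n_den <- sum(sel)
      data.frame(group_id = g,
                 index = if (n_den > 0) 100 * sum(num_pos[sel]) / n_den
                         else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_field = per_field, pooled = pooled, field_mean = field_mean,
       per_group = per_group)
}

#' Spheroid migration ratios
#'
#' Normalizes the invasive-area diameter of each spheroid-bearing well to
#' its own time-zero diameter and reports the mean ratio per time point
#' (optionally per group). Ratio at time zero is exactly 1 by
#' construction.
#'
#' @param measurements `data.frame` with columns `well_id`, `time_h`,
#'   `invasive_diameter` (micrometers, positive) and optionally
#'   `group_id`.
#' @return list with `per_well` (data.frame: well_id, time_h, ratio) and
#'   `group_mean` (data.frame: optional group_id, time_h, mean_ratio).
#' @export
migration_ratio <- function(measurements) {
  assert_that(is.data.frame(measurements) &&
                all(c("well_id", "time_h", "invasive_diameter") %in%
                      names(measurements)),
              "measurements needs well_id, time_h, invasive_diameter")
  assert_that(all(measurements$invasive_diameter > 0),
              "diameters must be positive")
  wells <- unique(measurements$well_id)
  per_well <- do.call(rbind, lapply(wells, function(w) {
    sub <- measurements[measurements$well_id == w, ]
    t0 <- sub$invasive_diameter[sub$time_h == 0]
    if (length(t0) == 0) abort("well '", w, "' has no time-0 diameter")
    if (length(t0) > 1) abort("well '", w, "' has multiple time-0 records")
    data.frame(well_id = w, time_h = sub$time_h,
               group_id = if ("group_id" %in% names(sub)) sub$group_id else NA,
               ratio = sub$invasive_diameter / t0,
               stringsAsFactors = FALSE)
  }))
  by_cols <- if ("group_id" %in% names(measurements)) {
    list(group_id = per_well$group_id, time_h = per_well$time_h)
  } else {
    list(time_h = per_well$time_h)
  }
  group_mean <- aggregate(list(mean_ratio = per_well$ratio), by_cols, mean)
  if (!"group_id" %in% names(measurements)) per_well$group_id <- NULL
  list(per_well = per_well, group_mean = group_mean)
}
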