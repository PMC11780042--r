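# The seven body-composition indices: L1 trabecular density mean/SD (a bone
# mineral density surrogate) and area, L3 SAT/SMA/VAT areas and SAT density
# SD.  Density statistics always come from the original HU slice, never from
# windowed values; the cortical class contributes to no index.

#' Area of one mask class in cm^2
#'
#' @param mask a [label_mask()].
#' @param class class name.
#' @param spacing pixel spacing in mm, length 2.
#' @return area in cm^2 (0 for an empty region).
#' @export
region_area <- function(mask, class, spacing) {
  stopifnot(inherits(mask, "label_mask"), length(spacing) == 2L)
  if (!class %in% mask$classes) stop("unknown class: ", class)
  n <- sum(mask$labels == (match(class, mask$classes) - 1L))
  n * spacing[1] * spacing[2] / 100
}

#' Density statistics of one mask class
#'
#' Mean and standard deviation (population convention, divide by N) of the HU
#' values under the class region.
#'
#' @param mask a [label_mask()].
#' @param class class name.
#' @param hu 2D HU matrix, same shape as the mask.
#' @return named numeric c(mean, sd), in HU.
#' @export
region_density_stats <- function(mask, class, hu) {
  stopifnot(inherits(mask, "label_mask"), all(dim(hu) == dim(mask$labels)))
  if (!class %in% mask$classes) stop("unknown class: ", class)
  sel <- mask$labels == (match(class, mask$classes) - 1L)
  if (!any(sel))
    stop_bodycomp(paste0("density statistics undefined: empty region '", class, "'"),
                  "bodycomp_undefined_statistic")
  v <- hu[sel]
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Compute the seven body-composition indices
#'
#' @param l1_mask [label_mask()] for the L1 slice (trabecular/cortical).
#' @param l1_hu HU matrix of the L1 slice (original HU, not windowed).
#' @param l3_mask [label_mask()] for the L3 slice (SMA/VAT/SAT).
#' @param l3_hu HU matrix of the L3 slice.
#' @param spacing pixel spacing in mm, length 2.
#' @param subject subject identifier.
#' @return an `index_report` with fields `bmd_avg` (HU), `bmd_sd` (HU),
#'   `l1_trab_area` (cm^2), `l3_sat_area` (cm^2), `l3_sma` (cm^2),
#'   `l3_vat_area` (cm^2), `l3_sat_density_sd` (HU).
#' @export
compute_report <- function(l1_mask, l1_hu, l3_mask, l3_hu, spacing,
                           subject = "anonymous") {
  trab <- region_density_stats(l1_mask, "trabecular", l1_hu)
  sat <- region_density_stats(l3_mask, "sat", l3_hu)
  structure(list(
    bmd_avg = unname(trab["mean"]),
    bmd_sd = unname(trab["sd"]),
    l1_trab_area = region_area(l1_mask, "trabecular", spacing),
    l3_sat_area = region_area(l3_mask, "sat", spacing),
    l3_sma = region_area(l3_mask, "sma", spacing),
    l3_vat_area = region_area(l3_mask, "vat", spacing),
    l3_sat_density_sd = unname(sat["sd"]),
    subject = subject), class = "index_report")
}

index_names <- c("bmd_avg", "bmd_sd", "l1_trab_area", "l3_sat_area",
                 "l3_sma", "l3_vat_area", "l3_sat_density_sd")

#' @export
as.data.frame.index_report <- function(x, ...) {
  data.frame(subject = x$subject,
             as.data.frame(x[index_names]),
             stringsAsFactors = FALSE)
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("<index_report> %s\n", x$subject))
  units <- c(bmd_avg = "HU", bmd_sd = "HU", l1_trab_area = "cm^2",
             l3_sat_area = "cm^2", l3_sma = "cm^2", l3_vat_area = "cm^2",
             l3_sat_density_sd = "HU")
  for (nm in index_names)
    cat(sprintf("  %-18s %8.2f %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

#' Write index reports as JSON or CSV
#'
#' @param reports an `index_report` or a list of them (batch mode).
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "index_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
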