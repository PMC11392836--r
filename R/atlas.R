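# 34 Desikan-Killiany cortical labels per hemisphere and their lobe
# assignments (Desikan lobe scheme). The insula has no lobe among the five
# analysis categories and defaults to "unassigned"; supply a custom mapping
# to absorb it into a lobe instead.
dk_base_labels <- c(
  bankssts = "temporal", caudalanteriorcingulate = "cingulate",
  caudalmiddlefrontal = "frontal", cuneus = "occipital",
  entorhinal = "temporal", fusiform = "temporal",
  inferiorparietal = "parietal", inferiortemporal = "temporal",
  isthmuscingulate = "cingulate", lateraloccipital = "occipital",
  lateralorbitofrontal = "frontal", lingual = "occipital",
  medialorbitofrontal = "frontal", middletemporal = "temporal",
  parahippocampal = "temporal", paracentral = "frontal",
  parsopercularis = "frontal", parsorbitalis = "frontal",
  parstriangularis = "frontal", pericalcarine = "occipital",
  postcentral = "parietal", posteriorcingulate = "cingulate",
  precentral = "frontal", precuneus = "parietal",
  rostralanteriorcingulate = "cingulate", rostralmiddlefrontal = "frontal",
  superiorfrontal = "frontal", superiorparietal = "parietal",
  superiortemporal = "temporal", supramarginal = "parietal",
  frontalpole = "frontal", temporalpole = "temporal",
  transversetemporal = "temporal", insula = "unassigned"
)

dk_lobes <- c("cingulate", "frontal", "occipital", "parietal", "temporal")

#' The ten lobar analysis regions
#'
#' @return Character vector of the 10 region labels
#'   (`left_cingulate`, ..., `right_temporal`).
#' @export
region_labels <- function() {
  as.vector(outer(c("left", "right"), dk_lobes, paste, sep = "_"))
}

new_region_mapping <- function(df) {
  df$region <- ifelse(df$lobe == "unassigned", NA_character_,
                      paste(df$hemisphere, df$lobe, sep = "_"))
  structure(df, class = c("region_mapping", "data.frame"))
}

#' Default 68-parcel to 10-region mapping
#'
#' Maps the 68 cortical Desikan-Killiany parcels (`lh_`/`rh_` prefixed) to
#' the ten analysis regions: {left, right} x {cingulate, frontal, occipital,
#' parietal, temporal}. The two insula parcels are left unassigned and drop
#' out of regional aggregation (they still count in parcel-level validity
#' bookkeeping).
#'
#' @return A `region_mapping` data frame with columns `parcel`,
#'   `hemisphere`, `lobe`, `region`.
#' @export
dk_region_mapping <- function() {
  new_region_mapping(data.frame(
    parcel = c(paste0("lh_", names(dk_base_labels)),
               paste0("rh_", names(dk_base_labels))),
    hemisphere = rep(c("left", "right"), each = length(dk_base_labels)),
    lobe = rep(unname(dk_base_labels), 2L),
    stringsAsFactors = FALSE
  ))
}

#' Load and validate a parcel-to-region mapping
#'
#' Reads a tab-separated table with columns `parcel`, `hemisphere`, `lobe`
#' and checks it against the 68 standard Desikan-Killiany labels: every
#' parcel present exactly once, hemispheres in {left, right}, lobes among
#' the five analysis lobes or `unassigned`.
#'
#' @param path Path to a TSV file.
#'
#' @return A `region_mapping` data frame.
#' @export
load_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parcel", "hemisphere", "lobe")
  if (!all(need %in% names(df))) {
    stop_alphapaf(sprintf("mapping must have columns %s",
                          paste(need, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  expected <- dk_region_mapping()$parcel
  dup <- df$parcel[duplicated(df$parcel)]
  if (length(dup)) {
    stop_alphapaf(sprintf("duplicate parcel entries: %s",
                          paste(unique(dup), collapse = ", ")),
                  "alphapaf_parse_error")
  }
  missing <- setdiff(expected, df$parcel)
  if (length(missing)) {
    stop_alphapaf(sprintf("mapping is missing parcels: %s",
                          paste(missing, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  unknown <- setdiff(df$parcel, expected)
  if (length(unknown)) {
    stop_alphapaf(sprintf("unknown parcels: %s", paste(unknown, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  bad_hemi <- df$parcel[!df$hemisphere %in% c("left", "right")]
  if (length(bad_hemi)) {
    stop_alphapaf(sprintf("invalid hemisphere for: %s",
                          paste(bad_hemi, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  bad_lobe <- df$parcel[!df$lobe %in% c(dk_lobes, "unassigned")]
  if (length(bad_lobe)) {
    stop_alphapaf(sprintf("invalid lobe for: %s", paste(bad_lobe, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  new_region_mapping(df[, need])
}

#' Aggregate parcel-level PAFs into the ten regions
#'
#' For each subject and region, averages the PAF over the region's valid
#' parcels (invalid parcels are excluded; a region with no valid parcel gets
#' a missing PAF) and averages relative alpha power over all of the region's
#' parcels. Unassigned parcels (insula in the default mapping) are dropped.
#'
#' @param parcel_fits Data frame from [estimate_paf_table()] (columns
#'   `subject_id`, `parcel`, `paf_hz`, `valid`, optionally `rel_alpha`).
#' @param mapping A `region_mapping` from [dk_region_mapping()] or
#'   [load_mapping()].
#'
#' @return Data frame with one row per subject x region: `subject_id`,
#'   `region`, `paf_hz`, `n_valid_parcels`, `n_total_parcels`, `rel_alpha`.
#' @export
aggregate_regions <- function(parcel_fits, mapping = dk_region_mapping()) {
  stopifnot(is.data.frame(parcel_fits),
            all(c("subject_id", "parcel", "paf_hz", "valid") %in% names(parcel_fits)))
  unmapped <- setdiff(unique(parcel_fits$parcel), mapping$parcel)
  if (length(unmapped)) {
    stop_alphapaf(sprintf("parcels not in mapping: %s",
                          paste(unmapped, collapse = ", ")),
                  "alphapaf_parse_error")
  }
  df <- parcel_fits
  df$region <- mapping$region[match(df$parcel, mapping$parcel)]
  df <- df[!is.na(df$region), , drop = FALSE]
  has_rel <- "rel_alpha" %in% names(df)
  subjects <- unique(parcel_fits$subject_id)
  sid <- factor(df$subject_id, levels = subjects)
  reg <- factor(df$region, levels = region_labels())
  ok <- df$valid & !is.na(df$paf_hz)
  n_total <- table(sid, reg)
  n_valid <- table(sid[ok], reg[ok])
  paf_sum <- tapply(df$paf_hz[ok], list(sid[ok], reg[ok]), sum, default = 0)
  paf_sum[is.na(paf_sum)] <- 0
  mean_paf <- ifelse(n_valid > 0, paf_sum / as.numeric(n_valid), NA_real_)
  rel_mean <- if (has_rel) {
    tapply(df$rel_alpha, list(sid, reg), mean, default = NA_real_)
  } else matrix(NA_real_, length(subjects), 10)
  out <- data.frame(
    subject_id = rep(subjects, times = 10L),
    region = rep(region_labels(), each = length(subjects)),
    paf_hz = as.vector(mean_paf),
    n_valid_parcels = as.vector(as.integer(n_valid)),
    n_total_parcels = as.vector(as.integer(n_total)),
    rel_alpha = as.vector(rel_mean),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Valid/invalid PAF counts by group or region
#'
#' Tabulates how many parcel-level spectra produced a valid PAF, split by
#' diagnosis group or by analysis region, with percentages at one decimal.
#' All parcels count, including unassigned ones when splitting by diagnosis.
#'
#' @param parcel_fits Data frame with columns `parcel`, `valid`, and (for
#'   `by = "diagnosis"`) a `diagnosis` column, e.g. [estimate_paf_table()]
#'   output merged with subject metadata.
#' @param by `"diagnosis"` or `"region"`.
#' @param mapping Mapping used when `by = "region"`.
#'
#' @return Data frame with columns `group`, `n_valid`, `n_invalid`,
#'   `n_total`, `pct_valid` (one decimal).
#' @export
validity_summary <- function(parcel_fits, by = c("diagnosis", "region"),
                             mapping = dk_region_mapping()) {
  by <- match.arg(by)
  if (nrow(parcel_fits) == 0L) {
    return(data.frame(group = character(), n_valid = integer(),
                      n_invalid = integer(), n_total = integer(),
                      pct_valid = numeric(), stringsAsFactors = FALSE))
  }
  if (by == "diagnosis") {
    stopifnot("diagnosis" %in% names(parcel_fits))
    g <- parcel_fits$diagnosis
  } else {
    g <- mapping$region[match(parcel_fits$parcel, mapping$parcel)]
  }
  keep <- !is.na(g)
  tab <- table(group = g[keep], valid = factor(parcel_fits$valid[keep],
                                               levels = c(FALSE, TRUE)))
  out <- data.frame(
    group = rownames(tab),
    n_valid = as.integer(tab[, "TRUE"]),
    n_invalid = as.integer(tab[, "FALSE"]),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_valid + out$n_invalid
  out$pct_valid <- round(100 * out$n_valid / out$n_total, 1)
  out
}
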