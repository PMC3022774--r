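#' Validate a qPCR panel of threshold-cycle values
#'
#' A panel is a long-format table of Ct measurements for a set of loci
#' across the three DNA fractions used for compartment localization:
#' `total`, `mt_enriched` (mitochondria-enriched) and `pt_enriched`
#' (plastid-enriched). Each locus carries a known compartment (`mt`, `pt`,
#' `nuc`) or `unknown` for query loci, and a per-locus amplification
#' efficiency. Every locus must be measured in every fraction; duplicate Ct
#' values further apart than `max_duplicate_spread` cycles are flagged.
#'
#' @param df Data frame with columns `locus_id`, `compartment`, `fraction`,
#'   `replicate`, `ct`, `efficiency`.
#' @param max_duplicate_spread Allowed within-duplicate Ct spread in cycles
#'   (default 1).
#' @return A tibble of class `qpcr_panel` (flagged rows carry
#'   `duplicate_flag = TRUE`).
#' @export
qpcr_panel <- function(df, max_duplicate_spread = 1) {
  need <- c("locus_id", "compartment", "fraction", "replicate", "ct",
            "efficiency")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- tibble::as_tibble(df)
  if (!all(out$fraction %in% c("total", "mt_enriched", "pt_enriched")))
    stop("fraction must be total / mt_enriched / pt_enriched", call. = FALSE)
  if (!all(out$compartment %in% c("mt", "pt", "nuc", "unknown")))
    stop("compartment must be mt / pt / nuc / unknown", call. = FALSE)
  cover <- dplyr::count(out, .data$locus_id, .data$fraction)
  full <- tidyr::expand_grid(locus_id = unique(out$locus_id),
                             fraction = c("total", "mt_enriched", "pt_enriched"))
  gap <- dplyr::anti_join(full, cover, by = c("locus_id", "fraction"))
  if (nrow(gap))
    stop("loci not measured in every fraction: ",
         paste(unique(gap$locus_id), collapse = ", "), call. = FALSE)
  spread <- out |>
    dplyr::group_by(.data$locus_id, .data$fraction) |>
    dplyr::mutate(duplicate_flag = (max(.data$ct) - min(.data$ct)) >
                    max_duplicate_spread) |>
    dplyr::ungroup()
  class(spread) <- c("qpcr_panel", setdiff(class(spread), "qpcr_panel"))
  spread
}

#' Relative template quantity from a Ct difference
#'
#' Standard efficiency-corrected quantification:
#' `ratio = (1 + E)^(ct_ref - ct_query)`. Efficiencies outside the accepted
#' window (0.9, 1.1] draw a warning, mirroring the >90% efficiency check
#' applied to qPCR assays.
#'
#' @param ct_query,ct_ref Threshold cycles of the query and reference.
#' @param efficiency Amplification efficiency `E` in (0, 1].
#' @return Fold-ratio of query to reference template.
#' @export
relative_quantity <- function(ct_query, ct_ref, efficiency = 1) {
  if (any(efficiency <= 0.9) || any(efficiency > 1.1))
    warning("amplification efficiency outside the accepted (0.9, 1.1] window",
            call. = FALSE)
  (1 + efficiency)^(ct_ref - ct_query)
}

#' Classify the genomic compartment of a locus from its qPCR profile
#'
#' Formalizes the copy-number argument for genome localization: the
#' mitochondrial, plastid and nuclear genomes differ widely in copies per
#' cell, and differential enrichment across the three DNA fractions
#' separates them further (the plastid-enriched fraction gives the greatest
#' separation and is up-weighted by default). Duplicate Cts are averaged;
#' Ct values are centered within each fraction (so the call is invariant to
#' adding a constant to all Cts of one fraction); the query's centered
#' 3-fraction profile is compared to each compartment's marker profile by a
#' weighted mean absolute Ct difference. The nearest compartment is called
#' when its margin over the runner-up reaches `margin_threshold` cycles,
#' otherwise the call is ambiguous.
#'
#' @param panel A `qpcr_panel`.
#' @param query Locus id to classify.
#' @param margin_threshold Ambiguity margin in cycles (default 2).
#' @param weights Named fraction weights (default plastid-enriched 2,
#'   others 1).
#' @return A one-row tibble of class `compartment_call`: `locus_id`, `call`
#'   (`mt`/`pt`/`nuc`/`ambiguous`), `dist_mt`, `dist_pt`, `dist_nuc`,
#'   `margin`.
#' @export
classify_compartment <- function(panel, query, margin_threshold = 2,
                                 weights = c(total = 1, mt_enriched = 1,
                                             pt_enriched = 2)) {
  fr <- c("total", "mt_enriched", "pt_enriched")
  mean_ct <- panel |>
    dplyr::group_by(.data$locus_id, .data$compartment, .data$fraction) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  if (!query %in% mean_ct$locus_id)
    stop("query locus '", query, "' not in panel", call. = FALSE)
  # center within fraction
  mean_ct <- mean_ct |>
    dplyr::group_by(.data$fraction) |>
    dplyr::mutate(ct_c = .data$ct - mean(.data$ct)) |>
    dplyr::ungroup()
  markers <- mean_ct |>
    dplyr::filter(.data$compartment %in% c("mt", "pt", "nuc"),
                  .data$locus_id != query) |>
    dplyr::group_by(.data$compartment, .data$fraction) |>
    dplyr::summarise(profile = mean(.data$ct_c), .groups = "drop")
  comps <- unique(markers$compartment)
  if (length(comps) < 2)
    stop("need marker loci for at least two compartments", call. = FALSE)
  qprof <- mean_ct[mean_ct$locus_id == query, ]
  qv <- setNames(qprof$ct_c, qprof$fraction)[fr]
  w <- weights[fr] / sum(weights[fr])
  dists <- vapply(c("mt", "pt", "nuc"), function(cp) {
    mk <- markers[markers$compartment == cp, ]
    if (nrow(mk) == 0) return(NA_real_)
    mv <- setNames(mk$profile, mk$fraction)[fr]
    sum(w * abs(qv - mv))
  }, numeric(1))
  ranked <- sort(dists[!is.na(dists)])
  margin <- if (length(ranked) >= 2) ranked[2] - ranked[1] else Inf
  call <- if (margin >= margin_threshold) names(ranked)[1] else "ambiguous"
  out <- tibble::tibble(locus_id = query, call = call,
                        dist_mt = dists["mt"], dist_pt = dists["pt"],
                        dist_nuc = dists["nuc"], margin = margin)
  class(out) <- c("compartment_call", class(out))
  out
}
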