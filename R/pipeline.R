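#' Classify gene copies as native or foreign by phylogenetic placement
#'
#' Fits an ML tree (GTR+Gamma+I), computes bootstrap support, roots at the
#' outgroup, and asks for every query record (those with `copy_class`
#' `"unknown"`) whether it is nested inside the donor clade (foreign) or
#' excluded from it (native). Support for either call is the bootstrap
#' percentage of the donor-group bipartition — the edge separating the donor
#' references together with any nested queries from the rest of the tree;
#' below `support_threshold` the record is left `"unknown"`. The
#' gene-duplication alternative is tested by constraining the foreign-called
#' records to be sister to the native recipient clade (keeping both groups'
#' observed internal structure) and comparing topologies with the SH test.
#'
#' @param aln A `gene_alignment` with donor-clade and outgroup reference
#'   records.
#' @param donor_taxa Taxa of the donor clade (reference side).
#' @param recipient_taxa Taxa of the recipient clade (the species carrying
#'   candidate copies).
#' @param outgroup_taxa Taxa used to root the tree.
#' @param n_bootstrap Bootstrap replicates (default 100).
#' @param support_threshold Minimum percent support to call (default 80).
#' @param test_duplication Run the constrained-topology SH test.
#' @param n_rell RELL draws for the SH test.
#' @param n_restarts ML search restarts.
#' @param seed RNG seed.
#' @return An object of class `copy_classification`: list with `calls`
#'   (tibble `id`, `taxon`, `copy_class`, `call`, `support`), `fit`
#'   (the `ml_fit`), `boot_tree`, `donor_group_support`, and `duplication`
#'   (tibble `p_sh`, `delta_loglik`, or `NULL`).
#' @export
classify_copies <- function(aln, donor_taxa, recipient_taxa, outgroup_taxa,
                            n_bootstrap = 100, support_threshold = 80,
                            test_duplication = TRUE, n_rell = 1000,
                            n_restarts = 5, seed = 1) {
  meta <- aln$meta
  stopifnot(any(meta$taxon %in% donor_taxa), any(meta$taxon %in% outgroup_taxa))
  fit <- ml_search(aln, n_restarts = n_restarts, seed = seed)
  btree <- bootstrap_support(aln, fit, n_replicates = n_bootstrap,
                             seed = seed + 1)
  queries <- meta$id[meta$copy_class == "unknown"]
  donor_ids <- meta$id[meta$taxon %in% donor_taxa & meta$copy_class != "unknown"]
  out_ids <- meta$id[meta$taxon %in% outgroup_taxa & meta$copy_class != "unknown"]
  rooted <- tryCatch(ape::root(btree, outgroup = out_ids, resolve.root = TRUE,
                               edgelabel = TRUE),
                     error = function(e) btree)
  donor_clade <- smallest_clade_containing(rooted, donor_ids,
                                           exclude = out_ids)
  # support of the donor-group bipartition on the *unrooted* boot-labeled tree
  grp_support <- clade_support_bipart(btree, donor_clade)
  calls <- tibble::tibble(
    id = queries,
    taxon = meta$taxon[match(queries, meta$id)],
    copy_class = meta$copy_class[match(queries, meta$id)],
    call = ifelse(queries %in% donor_clade, "foreign", "native"),
    support = grp_support)
  calls$call[is.na(calls$support) | calls$support < support_threshold] <- "unknown"
  duplication <- NULL
  foreign_ids <- calls$id[calls$call == "foreign"]
  native_rec_ids <- setdiff(meta$id[meta$taxon %in% recipient_taxa], foreign_ids)
  if (test_duplication && length(foreign_ids) >= 1 &&
      length(native_rec_ids) >= 1) {
    con <- constrain_duplication_tree(fit$tree, foreign_ids, native_rec_ids,
                                      out_ids)
    if (!is.null(con)) {
      tt <- topology_test(aln, list(fit$tree, con), fit$model, method = "SH",
                          n_rell = n_rell, seed = seed + 2)
      duplication <- tibble::tibble(p_sh = tt$table$p_value[2],
                                    delta_loglik = tt$table$delta[2])
    }
  }
  structure(list(calls = calls, fit = fit, boot_tree = btree,
                 donor_group_support = grp_support,
                 donor_clade_ids = donor_clade,
                 duplication = duplication),
            class = "copy_classification")
}

# smallest rooted clade containing all of `ids` but none of `exclude`
smallest_clade_containing <- function(rooted, ids, exclude = character(0)) {
  if (length(ids) == 1) return(ids)
  node <- ape::getMRCA(rooted, ids)
  tips <- ape::extract.clade(rooted, node)$tip.label
  if (any(tips %in% exclude)) return(ids)  # degenerate rooting; fall back
  tips
}

# bootstrap support of the bipartition tips | rest on a node-labeled tree
clade_support_bipart <- function(btree, tips) {
  other <- setdiff(btree$tip.label, tips)
  s1 <- clade_support(btree, tips)
  s2 <- clade_support(btree, other)   # same bipartition seen from the far side
  if (!is.na(s1)) s1 else s2
}

# Constrained alternative: the foreign group moved, as a unit with its
# observed internal structure, to be sister to the native recipient clade.
constrain_duplication_tree <- function(ml_tree, foreign_ids, native_rec_ids,
                                       out_ids) {
  tr <- tryCatch(ape::root(ml_tree, outgroup = out_ids, resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(tr)) return(NULL)
  sub <- ape::keep.tip(tr, foreign_ids)
  if (length(foreign_ids) == 1) {
    sub <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = foreign_ids, Nnode = 1L,
                          edge.length = 0.05), class = "phylo")
  }
  sub$root.edge <- 0.05
  pruned <- ape::drop.tip(tr, foreign_ids)
  if (is.null(pruned)) return(NULL)
  anchor <- if (length(native_rec_ids) > 1)
    ape::getMRCA(pruned, native_rec_ids)
  else match(native_rec_ids, pruned$tip.label)
  edge_i <- which(pruned$edge[, 2] == anchor)
  if (!length(edge_i)) return(NULL)
  pos <- min(0.02, pruned$edge.length[edge_i] / 2)
  con <- tryCatch(ape::bind.tree(pruned, sub, where = anchor, position = pos),
                  error = function(e) NULL)
  if (is.null(con)) return(NULL)
  con$edge.length[is.na(con$edge.length) | con$edge.length < 1e-8] <- 1e-8
  ape::unroot(con)
}

#' @export
print.copy_classification <- function(x, ...) {
  cat("<copy_classification> donor-group support ",
      x$donor_group_support, "%\n", sep = "")
  print(x$calls)
  if (!is.null(x$duplication))
    cat("duplication alternative: SH p = ",
        signif(x$duplication$p_sh, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy copy_classification
#' @export
tidy.copy_classification <- function(x, ...) x$calls

#' @method glance copy_classification
#' @export
glance.copy_classification <- function(x, ...) {
  tibble::tibble(n_queries = nrow(x$calls),
                 n_foreign = sum(x$calls$call == "foreign"),
                 n_native = sum(x$calls$call == "native"),
                 n_unknown = sum(x$calls$call == "unknown"),
                 donor_group_support = x$donor_group_support,
                 duplication_p_sh = if (is.null(x$duplication)) NA_real_
                 else x$duplication$p_sh)
}

#' Run the full HGT-forensics pipeline on a dataset
#'
#' Orchestrates all stages on a simulated (or identically structured)
#' dataset: per-gene copy classification with the duplication test,
#' conversion-tract detection for every foreign copy (donor reference as
#' parent A, co-resident native as parent B), edit-site retention and
#' mechanism classification against the donor-lineage edit evidence,
#' native/foreign pairwise divergence (tract codons excluded, edit sites
#' recoded), and qPCR compartment calls. Deterministic under the seed; the
#' report records the seed and replicate counts used.
#'
#' @param data A `sim_dataset` from [simulate_dataset()] (or a list with
#'   the same components: `alignments`, `edit_evidence`, `qpcr`, `config`).
#' @param donor_taxa,recipient_taxa,outgroup_taxa Taxon sets; defaults come
#'   from the simulation config.
#' @param n_bootstrap,support_threshold,n_rell,n_restarts Phylogenetic
#'   settings, see [classify_copies()].
#' @param n_permutations Conversion-scan permutations.
#' @param n_dnds_bootstrap Codon-bootstrap replicates for divergence SEs.
#' @param genes Genes to analyse (default all).
#' @param seed Global seed propagated to every stochastic stage.
#' @return An object of class `hgt_report`: list of tibbles
#'   (`classification`, `duplication`, `tracts`, `retention`, `divergence`,
#'   `compartments`) plus `provenance`.
#' @export
run_full_pipeline <- function(data, donor_taxa = NULL, recipient_taxa = NULL,
                              outgroup_taxa = NULL, n_bootstrap = 100,
                              support_threshold = 80, n_rell = 1000,
                              n_restarts = 5, n_permutations = 10000,
                              n_dnds_bootstrap = 500, genes = NULL, seed = 1) {
  cfg <- data$config
  if (is.null(donor_taxa))
    donor_taxa <- grep("^D", cfg$species_tree$tip.label, value = TRUE)
  if (is.null(recipient_taxa)) recipient_taxa <- rec_taxa(cfg)
  if (is.null(outgroup_taxa))
    outgroup_taxa <- grep("^O", cfg$species_tree$tip.label, value = TRUE)
  if (is.null(genes)) genes <- names(data$alignments)
  donor_rep <- if (!is.null(cfg$hgt_event)) cfg$hgt_event$donor else
    donor_taxa[1]
  class_rows <- list(); dup_rows <- list(); tract_rows <- list()
  ret_rows <- list(); div_rows <- list()
  for (g in genes) {
    aln <- data$alignments[[g]]
    cls <- classify_copies(aln, donor_taxa, recipient_taxa, outgroup_taxa,
                           n_bootstrap = n_bootstrap,
                           support_threshold = support_threshold,
                           n_rell = n_rell, n_restarts = n_restarts,
                           seed = seed)
    cr <- cls$calls; cr$gene <- g
    class_rows[[g]] <- cr
    if (!is.null(cls$duplication)) {
      dr <- cls$duplication; dr$gene <- g
      dup_rows[[g]] <- dr
    }
    foreign <- cr$id[cr$call == "foreign"]
    ev_g <- data$edit_evidence[data$edit_evidence$gene == g, , drop = FALSE]
    # predict edit sites in the donor-lineage representative, then tally
    # retention at the homologous positions in the foreign copies
    cm <- tibble::tibble(codon = seq_len(aln_length(aln) / 3),
                         col1 = seq(1, aln_length(aln), 3),
                         col2 = seq(2, aln_length(aln), 3),
                         col3 = seq(3, aln_length(aln), 3))
    pred <- if (nrow(ev_g)) predict_edit_sites(aln, donor_rep, ev_g, cm)
    else NULL
    for (f in foreign) {
      taxon_f <- cr$taxon[cr$id == f]
      native_id <- setdiff(aln$meta$id[aln$meta$taxon == taxon_f], f)[1]
      trip <- extract_informative_sites(aln, f, donor_rep, native_id)
      tracts <- if (trip$testable)
        detect_tracts(trip, n_permutations = n_permutations, seed = seed)
      else empty_tracts()
      for (k in seq_len(nrow(tracts))) {
        if (tracts$needs_au[k]) {
          tracts[k, ] <- confirm_long_tract(aln, tracts[k, ],
                                            n_restarts = 2, seed = seed)[
                                              , names(tracts)]
        }
      }
      if (nrow(tracts)) {
        tracts$gene <- g
        tract_rows[[paste(g, f)]] <- tracts
      }
      if (!is.null(pred) && nrow(pred)) {
        tly <- tryCatch(tally_retention(aln, f, pred), error = function(e) NULL)
        if (!is.null(tly)) {
          tly <- classify_mechanism(tly, cfg$background_c_to_t,
                                    cfg$edited_fraction)
          tly$gene <- g
          ret_rows[[paste(g, f)]] <- tly
        }
      }
    }
    # divergence between the two recipient-species pairs, native and foreign
    if (length(foreign) >= 2) {
      f2 <- foreign[1:2]
      taxa2 <- cr$taxon[match(f2, cr$id)]
      nat2 <- vapply(taxa2, function(tx)
        setdiff(aln$meta$id[aln$meta$taxon == tx], foreign)[1], character(1))
      ex_tr <- if (length(tract_rows)) dplyr::bind_rows(tract_rows) else NULL
      ex_tr <- if (!is.null(ex_tr)) ex_tr[ex_tr$gene == g, , drop = FALSE] else NULL
      ed_cols <- if (!is.null(pred)) pred$column else NULL
      dv_n <- tryCatch(pairwise_dnds(aln, nat2[1], nat2[2],
                                     edit_sites = ed_cols,
                                     n_bootstrap = n_dnds_bootstrap,
                                     seed = seed),
                       error = function(e) NULL)
      dv_f <- tryCatch(pairwise_dnds(aln, f2[1], f2[2], edit_sites = ed_cols,
                                     exclude_tracts = ex_tr,
                                     n_bootstrap = n_dnds_bootstrap,
                                     seed = seed),
                       error = function(e) NULL)
      if (!is.null(dv_n)) { dv_n$gene <- g; dv_n$copy <- "native" }
      if (!is.null(dv_f)) { dv_f$gene <- g; dv_f$copy <- "foreign" }
      div_rows[[g]] <- dplyr::bind_rows(dv_n, dv_f)
    }
  }
  # pooled mechanism verdict per foreign copy across genes (the per-gene
  # site counts can be tiny; pooling mirrors tallying all assessable sites
  # of the transferred segment together)
  ret_pooled <- NULL
  if (length(ret_rows)) {
    ret_all <- dplyr::bind_rows(ret_rows)
    ret_pooled <- ret_all |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(n_sites_assessed = sum(.data$n_sites_assessed),
                       n_C = sum(.data$n_C), n_T = sum(.data$n_T),
                       n_other = sum(.data$n_other),
                       n_outside_span = sum(.data$n_outside_span),
                       .groups = "drop") |>
      dplyr::mutate(verdict = NA_character_, verdict_p = NA_real_)
    class(ret_pooled) <- c("retention_tally", class(ret_pooled))
    ret_pooled <- dplyr::bind_rows(lapply(seq_len(nrow(ret_pooled)),
                                          function(i) classify_mechanism(
                                            ret_pooled[i, ],
                                            cfg$background_c_to_t,
                                            cfg$edited_fraction)))
  }
  comp_rows <- NULL
  if (!is.null(data$qpcr)) {
    qloci <- unique(data$qpcr$locus_id[data$qpcr$compartment == "unknown"])
    comp_rows <- dplyr::bind_rows(lapply(qloci, function(q)
      classify_compartment(data$qpcr, q)))
  }
  structure(list(
    classification = dplyr::bind_rows(class_rows),
    duplication = if (length(dup_rows)) dplyr::bind_rows(dup_rows) else NULL,
    tracts = if (length(tract_rows)) dplyr::bind_rows(tract_rows)
    else empty_tracts(),
    retention = if (length(ret_rows)) dplyr::bind_rows(ret_rows) else NULL,
    retention_pooled = ret_pooled,
    divergence = if (length(div_rows)) dplyr::bind_rows(div_rows) else NULL,
    compartments = comp_rows,
    provenance = list(seed = seed, n_bootstrap = n_bootstrap,
                      n_rell = n_rell, n_permutations = n_permutations,
                      n_dnds_bootstrap = n_dnds_bootstrap,
                      compartment_assessed = !is.null(data$qpcr))),
    class = "hgt_report")
}

#' @export
print.hgt_report <- function(x, ...) {
  cat("<hgt_report> seed", x$provenance$seed, "\n")
  cat("- copies:", sum(x$classification$call == "foreign"), "foreign /",
      sum(x$classification$call == "native"), "native /",
      sum(x$classification$call == "unknown"), "unknown\n")
  cat("- conversion tracts:", nrow(x$tracts), "\n")
  if (!is.null(x$retention))
    cat("- mechanism verdicts:",
        paste(unique(x$retention$verdict), collapse = ", "), "\n")
  if (!is.null(x$compartments))
    cat("- compartment calls:",
        paste(x$compartments$locus_id, x$compartments$call, sep = ":",
              collapse = ", "), "\n")
  else cat("- compartments: not assessed\n")
  invisible(x)
}

#' Write an hgt_report to disk (JSON plus TSV tables)
#' @param report An `hgt_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("classification", "duplication", "tracts", "retention",
            "retention_pooled", "divergence", "compartments")
  for (nm in tabs) {
    if (!is.null(report[[nm]]) && nrow(report[[nm]]) > 0)
      utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- lapply(report[tabs], function(x) if (is.null(x)) NULL else
    as.data.frame(x))
  json$provenance <- report$provenance
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
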