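#' Simulation configuration for a synthetic HGT study
#'
#' Defines the generative model used by [simulate_dataset()]: protein-coding
#' genes evolve along a known species tree under a GTR nucleotide process
#' with omega-dependent acceptance of non-synonymous changes; one horizontal
#' transfer grafts the donor-lineage sequence into the recipient clade as a
#' second ("foreign") locus, which thereafter evolves as a pseudogene
#' (relaxed selection, elevated rate, frameshifting deletions, premature
#' stops allowed); C-to-U edit sites carry genomic `C` in all functional
#' lineages; the transfer mechanism sets the edit-site states of the foreign
#' copies (`DNA`: `C` up to background substitution; `RNA`: `T` at the
#' fully-edited fraction); gene-conversion tracts overwrite a span of a
#' foreign copy with a partner's current sequence; and a qPCR panel is drawn
#' from three-genome copy-number structure.
#'
#' The default taxon set mirrors a parasite-to-host transfer study design:
#' a donor clade of four species (`D1`-`D4`), a recipient clade of three
#' (`R1`-`R3`, each contributing a native and a foreign copy candidate) and
#' two outgroups (`O1`, `O2`). Default gene lengths match typical plant
#' mitochondrial genes (atp1 424, atp6 205, matR 626 codons) and default
#' edit-site counts per gene are 1, 15 and 10.
#'
#' @param species_tree Newick string or `phylo` for the native species tree
#'   (branch lengths in substitutions/site).
#' @param gene_lengths Named integer vector of codons per gene.
#' @param gtr A `gtr_model` for the nucleotide process.
#' @param omega_functional dN/dS acceptance for functional copies (< 1).
#' @param omega_pseudo dN/dS acceptance after pseudogenization (default 1).
#' @param rate_multiplier_pseudo Rate multiplier for pseudogene branches.
#' @param hgt_event List: `donor` (tip whose terminal branch donates),
#'   `recipients` (tips of the recipient clade), `time_fraction` (position
#'   of the transfer along the donor branch). `NULL` disables the transfer.
#' @param indel_rate_pseudo Deletion events per site per substitution/site
#'   on pseudogene branches.
#' @param edit_sites_per_gene Named integer vector (same names as
#'   `gene_lengths`).
#' @param mechanism `"DNA"` or `"RNA"`.
#' @param edited_fraction Fully-edited fraction under an RNA intermediate.
#' @param background_c_to_t Background C-to-T substitution probability at
#'   edit sites per foreign tip.
#' @param conversion_tracts Tibble with `gene`, `start_codon`, `end_codon`,
#'   `partner` (`"native"` or `"distant_native"`), `tip` (recipient tip
#'   whose foreign copy is converted); zero rows for none.
#' @param qpcr List: `copy_number` (named `nuc`/`mt`/`pt` copies per cell),
#'   `enrichment_mt`, `enrichment_pt` (fold enrichment of the respective
#'   genome in its enriched fraction), `efficiency`, `ct_noise_sd`,
#'   `intercept` (Ct of one template copy).
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    species_tree = default_species_tree(),
    gene_lengths = c(atp1 = 424, atp6 = 205, matR = 626),
    gtr = gtr_model(rates = c(1, 3, 1, 1, 3, 1),
                    base_freqs = c(0.28, 0.22, 0.22, 0.28), shape = 1, k = 4),
    omega_functional = 0.2,
    omega_pseudo = 1,
    rate_multiplier_pseudo = 40,
    hgt_event = list(donor = "D1", recipients = c("R1", "R2", "R3"),
                     time_fraction = 0.5),
    indel_rate_pseudo = 0.02,
    edit_sites_per_gene = c(atp1 = 1, atp6 = 15, matR = 10),
    mechanism = c("DNA", "RNA"),
    edited_fraction = 0.9,
    background_c_to_t = 0.02,
    conversion_tracts = tibble::tibble(gene = "atp1", start_codon = 50L,
                                       end_codon = 62L, partner = "native",
                                       tip = "R1"),
    qpcr = list(copy_number = c(nuc = 2, mt = 50, pt = 500),
                enrichment_mt = 20, enrichment_pt = 10,
                efficiency = 1, ct_noise_sd = 0.3, intercept = 34),
    seed = 1) {
  mechanism <- match.arg(mechanism)
  if (is.character(species_tree)) species_tree <- ape::read.tree(text = species_tree)
  stopifnot(inherits(species_tree, "phylo"), !is.null(species_tree$edge.length),
            all(names(edit_sites_per_gene) == names(gene_lengths)),
            omega_functional > 0, rate_multiplier_pseudo >= 1,
            is.numeric(seed))
  if (!is.null(hgt_event)) {
    stopifnot(hgt_event$donor %in% species_tree$tip.label,
              all(hgt_event$recipients %in% species_tree$tip.label))
  }
  structure(list(species_tree = species_tree, gene_lengths = gene_lengths,
                 gtr = gtr, omega_functional = omega_functional,
                 omega_pseudo = omega_pseudo,
                 rate_multiplier_pseudo = rate_multiplier_pseudo,
                 hgt_event = hgt_event, indel_rate_pseudo = indel_rate_pseudo,
                 edit_sites_per_gene = edit_sites_per_gene,
                 mechanism = mechanism, edited_fraction = edited_fraction,
                 background_c_to_t = background_c_to_t,
                 conversion_tracts = conversion_tracts, qpcr = qpcr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((O1:0.15,O2:0.15):0.05,",
    "(((D1:0.02,D2:0.02):0.03,(D3:0.03,D4:0.03):0.02):0.10,",
    "((R1:0.002,R2:0.002):0.001,R3:0.003):0.10):0.02);"))
}

# --- integer-coded sequence machinery ---------------------------------------

.base4 <- c("A", "C", "G", "T")

codon_idx_tables <- function() {
  if (is.null(.xt_cache$aa64)) {
    code <- genetic_code()
    aa <- character(64); cods <- character(64)
    for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
      idx <- 16 * (i1 - 1) + 4 * (i2 - 1) + i3
      cods[idx] <- paste0(.base4[i1], .base4[i2], .base4[i3])
      aa[idx] <- code[cods[idx]]
    }
    .xt_cache$aa64 <- aa
    .xt_cache$stop64 <- aa == "*"
    .xt_cache$cod64 <- cods
  }
  list(aa = .xt_cache$aa64, stop = .xt_cache$stop64, cod = .xt_cache$cod64)
}

codon_at <- function(seq_int, ci) {
  16 * (seq_int[3 * ci - 2] - 1) + 4 * (seq_int[3 * ci - 1] - 1) + seq_int[3 * ci]
}

random_coding_seq <- function(n_codons, bf) {
  tab <- codon_idx_tables()
  out <- integer(3 * n_codons)
  for (ci in seq_len(n_codons)) {
    repeat {
      tri <- sample.int(4, 3, replace = TRUE, prob = bf)
      idx <- 16 * (tri[1] - 1) + 4 * (tri[2] - 1) + tri[3]
      if (!tab$stop[idx]) break
    }
    out[(3 * ci - 2):(3 * ci)] <- tri
  }
  out
}

# Evolve a coding sequence for branch length t (expected substitutions per
# site at the neutral scale). Proposals follow the GTR process; non-
# synonymous proposals are accepted with probability omega; proposals
# creating stop codons are rejected unless allow_stops. Positions with
# weight 0 (protected edit sites) never mutate.
evolve_coding <- function(seq_int, t, model, omega, site_w = NULL,
                          allow_stops = FALSE) {
  L <- length(seq_int)
  tab <- codon_idx_tables()
  prow <- -model$Q; diag(prow) <- 0
  prow <- prow / rowSums(prow)
  n_target <- rpois(1, t * L)
  syn <- 0L; nonsyn <- 0L
  if (n_target == 0) {
    return(list(seq = seq_int, syn = 0L, nonsyn = 0L))
  }
  uniform <- is.null(site_w)
  queue <- integer(0); qpos <- 1L
  draw_pos <- function() {
    if (qpos > length(queue)) {
      queue <<- if (uniform) sample.int(L, 256L, replace = TRUE)
      else sample.int(L, 256L, replace = TRUE, prob = site_w)
      qpos <<- 1L
    }
    p <- queue[qpos]; qpos <<- qpos + 1L
    p
  }
  applied <- 0L; tries <- 0L; max_tries <- 200L * n_target + 1000L
  while (applied < n_target && tries < max_tries) {
    tries <- tries + 1L
    pos <- draw_pos()
    b <- seq_int[pos]
    nb <- sample.int(4, 1, prob = prow[b, ])
    ci <- (pos - 1L) %/% 3L + 1L
    old_idx <- codon_at(seq_int, ci)
    tmp <- seq_int[(3 * ci - 2):(3 * ci)]
    tmp[pos - 3 * (ci - 1L)] <- nb
    new_idx <- 16 * (tmp[1] - 1) + 4 * (tmp[2] - 1) + tmp[3]
    if (tab$stop[new_idx] && !allow_stops) next
    is_syn <- tab$aa[old_idx] == tab$aa[new_idx]
    if (!is_syn && runif(1) > omega) next
    seq_int[pos] <- nb
    applied <- applied + 1L
    if (is_syn) syn <- syn + 1L else nonsyn <- nonsyn + 1L
  }
  list(seq = seq_int, syn = syn, nonsyn = nonsyn)
}

int_to_res <- function(seq_int) .base4[seq_int]

#' Simulate a full synthetic HGT dataset with ground truth
#'
#' Generates, per gene, an alignment of native copies for every species plus
#' foreign (transferred) copies in the recipient clade, together with the
#' edit-evidence tables of the reference species, a qPCR panel and a truth
#' ledger covering every generated record. Byte-identical under a fixed
#' seed. Deletions (the pseudogene indels) are placed away from edit sites
#' and conversion-tract spans so that every configured tract is realizable;
#' because natives are never deleted, alignment columns coincide with gene
#' coordinates.
#'
#' @param cfg A `sim_config`.
#' @return A list of class `sim_dataset` with `alignments` (named list of
#'   `gene_alignment`), `edit_evidence` (an `edit_evidence` tibble over the
#'   reference species), `qpcr` (a `qpcr_panel`), and `truth` (list:
#'   `foreign_ids`, `donor_rep`, per-gene `edit_sites` tibble with the
#'   foreign-tip states, `tracts` with implanted and realized
#'   informative-site spans, `deletions`, `mechanism`, `qpcr_compartment`,
#'   `species_tree`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tr <- ape::reorder.phylo(cfg$species_tree, "cladewise")
  ntip <- length(tr$tip.label)
  genes <- names(cfg$gene_lengths)
  alignments <- list()
  edit_rows <- list()
  truth_edit <- list()
  truth_tracts <- list()
  truth_dels <- list()
  rec <- if (is.null(cfg$hgt_event)) character(0) else cfg$hgt_event$recipients
  foreign_ids <- list()
  for (g in genes) {
    Lc <- cfg$gene_lengths[[g]]
    Ln <- 3L * Lc
    sim <- simulate_gene(cfg, g, Lc, tr)
    alignments[[g]] <- sim$alignment
    foreign_ids[[g]] <- sim$foreign_ids
    edit_rows[[g]] <- sim$edit_evidence
    truth_edit[[g]] <- sim$edit_truth
    truth_tracts[[g]] <- sim$tract_truth
    truth_dels[[g]] <- sim$deletion_truth
  }
  qp <- simulate_qpcr_panel(cfg$qpcr, seed = cfg$seed + 104729L)
  truth <- list(
    foreign_ids = unlist(foreign_ids, use.names = FALSE),
    foreign_ids_by_gene = foreign_ids,
    donor_rep = if (is.null(cfg$hgt_event)) NA_character_ else cfg$hgt_event$donor,
    recipients = rec,
    edit_sites = dplyr::bind_rows(truth_edit),
    tracts = dplyr::bind_rows(truth_tracts),
    deletions = dplyr::bind_rows(truth_dels),
    mechanism = cfg$mechanism,
    qpcr_compartment = attr(qp, "truth_compartment"),
    species_tree = tr)
  structure(list(alignments = alignments,
                 edit_evidence = edit_evidence(dplyr::bind_rows(edit_rows)),
                 qpcr = qp, truth = truth, config = cfg),
            class = "sim_dataset")
}

simulate_gene <- function(cfg, g, Lc, tr) {
  Ln <- 3L * Lc
  ntip <- length(tr$tip.label)
  model <- cfg$gtr
  bf <- model$base_freqs
  # per-site rate categories (discrete gamma)
  site_rate <- sample(model$cat_rates, Ln, replace = TRUE)
  # edit sites: codon position 2, genomic C, C->T non-synonymous
  n_edit <- cfg$edit_sites_per_gene[[g]]
  tract_cfg <- cfg$conversion_tracts
  tract_cfg <- tract_cfg[tract_cfg$gene == g, , drop = FALSE]
  tract_codons <- integer(0)
  if (nrow(tract_cfg)) {
    stopifnot(all(tract_cfg$end_codon <= Lc), all(tract_cfg$start_codon >= 1))
    for (i in seq_len(nrow(tract_cfg)))
      tract_codons <- union(tract_codons,
                            seq(tract_cfg$start_codon[i], tract_cfg$end_codon[i]))
  }
  avail_codons <- setdiff(seq(3, Lc - 2), tract_codons)
  edit_codons <- sort(sample(avail_codons, n_edit))
  edit_cols <- 3L * edit_codons - 1L   # codon position 2
  root_seq <- random_coding_seq(Lc, bf)
  for (ci in edit_codons) {
    root_seq[3 * ci - 1] <- 2L  # C (A=1,C=2,G=3,T=4)
  }
  w <- site_rate
  w[edit_cols] <- 0               # edit sites protected; states set explicitly
  w <- w / mean(w[w > 0])
  # evolve natives down the tree
  node_seq <- vector("list", ntip + tr$Nnode)
  root <- ntip + 1L
  node_seq[[root]] <- root_seq
  edge_ord <- seq_len(nrow(tr$edge))  # cladewise: parents before children
  for (e in edge_ord) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    ev <- evolve_coding(node_seq[[par]], tr$edge.length[e], model,
                        cfg$omega_functional, site_w = w, allow_stops = FALSE)
    node_seq[[child]] <- ev$seq
  }
  tips <- tr$tip.label
  seqs <- list()
  for (i in seq_len(ntip)) seqs[[tips[i]]] <- node_seq[[i]]
  foreign <- list(); del_mask <- list(); del_truth <- list()
  if (!is.null(cfg$hgt_event)) {
    hg <- cfg$hgt_event
    di <- match(hg$donor, tips)
    dedge <- which(tr$edge[, 2] == di)
    tlen <- tr$edge.length[dedge]
    ev <- evolve_coding(node_seq[[tr$edge[dedge, 1]]], hg$time_fraction * tlen,
                        model, cfg$omega_functional, site_w = w,
                        allow_stops = FALSE)
    transfer_seq <- ev$seq
    # mechanism fixes edit-site states of the transferred molecule
    if (cfg$mechanism == "RNA") {
      edited <- runif(length(edit_cols)) < cfg$edited_fraction
      transfer_seq[edit_cols[edited]] <- 4L  # T
    }
    # evolve the foreign locus down the recipient subtree (pseudogene)
    sub <- ape::keep.tip(tr, hg$recipients)
    stn <- length(sub$tip.label)
    sub_seq <- vector("list", stn + sub$Nnode)
    sub_del <- vector("list", stn + sub$Nnode)
    sroot <- stn + 1L
    sub_seq[[sroot]] <- transfer_seq
    sub_del[[sroot]] <- rep(FALSE, Ln)
    tract_cols_all <- if (length(tract_codons))
      sort(unique(c(outer(3 * tract_codons - 2, 0:2, "+")))) else integer(0)
    for (e in seq_len(nrow(sub$edge))) {
      par <- sub$edge[e, 1]; child <- sub$edge[e, 2]
      t_b <- sub$edge.length[e] * cfg$rate_multiplier_pseudo
      ev <- evolve_coding(sub_seq[[par]], t_b, model, cfg$omega_pseudo,
                          site_w = w, allow_stops = TRUE)
      child_seq <- ev$seq
      child_del <- sub_del[[par]]
      n_del <- rpois(1, cfg$indel_rate_pseudo * Ln * t_b)
      if (n_del > 0) {
        for (d in seq_len(n_del)) {
          len <- sample(c(1L, 2L, 4L, 5L), 1, prob = c(0.45, 0.3, 0.15, 0.1))
          ok <- setdiff(seq(4L, Ln - len - 3L),
                        c(edit_cols, tract_cols_all,
                          unlist(lapply(c(edit_cols, tract_cols_all),
                                        function(p) (p - len):p))))
          if (!length(ok)) next
          st <- sample(ok, 1)
          child_del[st:(st + len - 1L)] <- TRUE
          del_truth[[length(del_truth) + 1L]] <- tibble::tibble(
            gene = g, tip = NA_character_, node = child, start = st,
            length = len, frameshifting = (len %% 3L != 0L))
        }
      }
      sub_seq[[child]] <- child_seq
      sub_del[[child]] <- child_del
    }
    for (i in seq_len(stn)) {
      tip <- sub$tip.label[i]
      id <- paste0(tip, "_hgt")
      s <- sub_seq[[i]]
      # per-tip background C->T at edit sites (post-transfer substitutions)
      isC <- edit_cols[s[edit_cols] == 2L]
      if (length(isC)) {
        flip <- isC[runif(length(isC)) < cfg$background_c_to_t]
        s[flip] <- 4L
      }
      foreign[[id]] <- s
      del_mask[[id]] <- sub_del[[i]]
    }
    if (length(del_truth)) {
      # resolve node numbers to the tips below them
      for (k in seq_along(del_truth)) {
        nd <- del_truth[[k]]$node
        below <- if (nd <= stn) sub$tip.label[nd] else
          paste(ape::extract.clade(sub, nd)$tip.label, collapse = "+")
        del_truth[[k]]$tip <- below
        del_truth[[k]]$node <- NULL
      }
    }
    # conversion tracts overwrite the foreign copy with the partner sequence
    if (nrow(tract_cfg)) {
      for (i in seq_len(nrow(tract_cfg))) {
        tc <- tract_cfg[i, ]
        cols <- (3 * tc$start_codon - 2):(3 * tc$end_codon)
        id <- paste0(tc$tip, "_hgt")
        partner_seq <- if (tc$partner == "native") seqs[[tc$tip]] else
          seqs[[setdiff(tips, c(hg$recipients, hg$donor))[1]]]
        foreign[[id]][cols] <- partner_seq[cols]
      }
    }
  }
  # assemble alignment
  all_ids <- c(tips, names(foreign))
  mat <- matrix("-", nrow = length(all_ids), ncol = Ln,
                dimnames = list(all_ids, NULL))
  for (tp in tips) mat[tp, ] <- int_to_res(seqs[[tp]])
  for (id in names(foreign)) {
    row <- int_to_res(foreign[[id]])
    row[del_mask[[id]]] <- "-"
    mat[id, ] <- row
  }
  is_rec <- all_ids %in% rec_taxa(cfg)
  meta <- tibble::tibble(
    id = all_ids,
    taxon = sub("_hgt$", "", all_ids),
    line = "A", gene = g,
    copy_class = dplyr::case_when(
      grepl("_hgt$", all_ids) ~ "unknown",
      sub("_hgt$", "", all_ids) %in% rec_taxa(cfg) ~ "unknown",
      TRUE ~ "reference"))
  aln <- gene_alignment(mat, meta)
  # edit evidence from reference species (donor clade minus the transfer
  # representative, plus outgroups) — all carry genomic C at the sites
  donor <- if (is.null(cfg$hgt_event)) character(0) else cfg$hgt_event$donor
  ref_ids <- setdiff(meta$id[meta$copy_class == "reference"], donor)
  ev <- tidyr::expand_grid(reference_id = ref_ids, column = edit_cols) |>
    dplyr::mutate(gene = g, evidence = "experimental", codon_position = 2L) |>
    dplyr::select("reference_id", "gene", "column", "evidence",
                  "codon_position")
  edit_truth <- if (length(foreign)) {
    et <- tidyr::expand_grid(id = names(foreign), column = edit_cols)
    et$gene <- g
    et$state <- mat[cbind(match(et$id, rownames(mat)), et$column)]
    et
  } else {
    tibble::tibble(id = character(), column = integer(), gene = character(),
                   state = character())
  }
  tract_truth <- NULL
  if (!is.null(cfg$hgt_event) && nrow(tract_cfg)) {
    tract_truth <- tract_cfg
    tract_truth$query_id <- paste0(tract_cfg$tip, "_hgt")
    tract_truth$implanted_start <- 3L * tract_cfg$start_codon - 2L
    tract_truth$implanted_end <- 3L * tract_cfg$end_codon
    # observable truth: first/last informative site supporting the partner
    # inside the implanted span (tract coordinates are reported between
    # supporting sites)
    tract_truth$start <- NA_integer_; tract_truth$end <- NA_integer_
    tract_truth$n_informative <- 0L
    for (i in seq_len(nrow(tract_truth))) {
      qid <- tract_truth$query_id[i]
      pa <- aln_seq(aln, donor)
      pb <- if (tract_cfg$partner[i] == "native") aln_seq(aln, tract_cfg$tip[i])
      else aln_seq(aln, setdiff(tips, c(cfg$hgt_event$recipients, donor))[1])
      q <- aln_seq(aln, qid)
      span <- tract_truth$implanted_start[i]:tract_truth$implanted_end[i]
      inf <- span[pa[span] != pb[span] & q[span] == pb[span] &
                    pa[span] %in% .base4 & pb[span] %in% .base4 &
                    q[span] %in% .base4]
      if (length(inf)) {
        tract_truth$start[i] <- min(inf)
        tract_truth$end[i] <- max(inf)
        tract_truth$n_informative[i] <- length(inf)
      }
    }
  }
  list(alignment = aln, foreign_ids = names(foreign), edit_evidence = ev,
       edit_truth = edit_truth,
       tract_truth = tract_truth,
       deletion_truth = if (length(del_truth)) dplyr::bind_rows(del_truth)
       else NULL)
}

rec_taxa <- function(cfg) {
  if (is.null(cfg$hgt_event)) character(0) else cfg$hgt_event$recipients
}

#' Simulate a qPCR panel from three-genome copy-number structure
#'
#' Marker loci (2 nuclear, 2 mitochondrial, 2 plastid) and three query loci
#' at mitochondrial copy number are measured in duplicate across the three
#' DNA fractions. `Ct = intercept - log(copies x enrichment)/log(1 + E) +
#' noise`.
#'
#' @param qcfg The `qpcr` component of a [sim_config()].
#' @param seed RNG seed.
#' @return A `qpcr_panel`; the true compartment of every locus is attached
#'   as attribute `"truth_compartment"`.
#' @export
simulate_qpcr_panel <- function(qcfg, seed = 1) {
  set.seed(seed)
  loci <- tibble::tibble(
    locus_id = c("nuc_marker1", "nuc_marker2", "mt_marker1", "mt_marker2",
                 "pt_marker1", "pt_marker2", "foreign_atp1", "foreign_atp6",
                 "foreign_matR"),
    true_comp = c("nuc", "nuc", "mt", "mt", "pt", "pt", "mt", "mt", "mt"),
    declared = c("nuc", "nuc", "mt", "mt", "pt", "pt", "unknown", "unknown",
                 "unknown"))
  E <- qcfg$efficiency
  rows <- list()
  for (fr in c("total", "mt_enriched", "pt_enriched")) {
    for (i in seq_len(nrow(loci))) {
      cp <- qcfg$copy_number[[loci$true_comp[i]]]
      enr <- 1
      if (fr == "mt_enriched" && loci$true_comp[i] == "mt") enr <- qcfg$enrichment_mt
      if (fr == "pt_enriched" && loci$true_comp[i] == "pt") enr <- qcfg$enrichment_pt
      ct0 <- qcfg$intercept - log(cp * enr) / log(1 + E)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        locus_id = loci$locus_id[i], compartment = loci$declared[i],
        fraction = fr, replicate = 1:2,
        ct = ct0 + rnorm(2, 0, qcfg$ct_noise_sd), efficiency = E)
    }
  }
  panel <- qpcr_panel(dplyr::bind_rows(rows))
  attr(panel, "truth_compartment") <- setNames(loci$true_comp, loci$locus_id)
  panel
}

#' Simulate a xenolog triplet with an optional implanted conversion tract
#'
#' Two parent lineages diverge from a common ancestor by
#' `parent_divergence` substitutions/site in total; the query then evolves
#' from parent A by `query_divergence`. With a `tract`, the query's span is
#' overwritten by parent B's current sequence (the implanted conversion).
#' Evolution is neutral (no codon structure), matching the information
#' actually used by the run-statistic test. The truth attribute records the
#' implanted span and its realized first/last informative supporting
#' columns (tract coordinates are reported between supporting sites).
#'
#' @param n_sites Alignment length in nucleotides.
#' @param parent_divergence Total divergence between parents (subs/site).
#' @param query_divergence Divergence of query from parent A.
#' @param tract `NULL` or `c(start, end)` columns to implant.
#' @param model A `gtr_model` (default Jukes-Cantor-like).
#' @param seed RNG seed.
#' @return A `gene_alignment` with records `parentA`, `parentB`, `query`
#'   and attribute `"truth"` (list: `implanted`, `start`, `end`,
#'   `n_informative`).
#' @export
simulate_triplet <- function(n_sites, parent_divergence = 0.1,
                             query_divergence = 0.02, tract = NULL,
                             model = gtr_model(), seed = 1) {
  set.seed(seed)
  bf <- model$base_freqs
  anc <- sample.int(4, n_sites, replace = TRUE, prob = bf)
  ev <- function(s, t) evolve_neutral(s, t, model)
  pa <- ev(anc, parent_divergence / 2)
  pb <- ev(anc, parent_divergence / 2)
  q <- ev(pa, query_divergence)
  truth <- list(implanted = tract, start = NA_integer_, end = NA_integer_,
                n_informative = 0L)
  if (!is.null(tract)) {
    span <- tract[1]:tract[2]
    q[span] <- pb[span]
    inf <- span[pa[span] != pb[span]]   # q matches pb there by construction
    if (length(inf)) truth <- list(implanted = tract, start = min(inf),
                                   end = max(inf), n_informative = length(inf))
  }
  aln <- gene_alignment(rbind(parentA = int_to_res(pa),
                              parentB = int_to_res(pb),
                              query = int_to_res(q)))
  attr(aln, "truth") <- truth
  aln
}

evolve_neutral <- function(seq_int, t, model) {
  L <- length(seq_int)
  prow <- -model$Q; diag(prow) <- 0
  prow <- prow / rowSums(prow)
  n <- rpois(1, t * L)
  if (n == 0) return(seq_int)
  pos <- sample.int(L, n, replace = TRUE)
  for (i in seq_len(n)) {
    b <- seq_int[pos[i]]
    seq_int[pos[i]] <- sample.int(4, 1, prob = prow[b, ])
  }
  seq_int
}

#' Simulate a coding sequence pair at a known synonymous divergence
#'
#' Evolves a descendant from a random ancestor by applying a
#' Poisson-distributed number of accepted synonymous
#' (`mean = ds_true x S0`) and non-synonymous (`mean = omega x ds_true x
#' N0`) substitutions, where `S0`/`N0` are the ancestor's Nei-Gojobori site
#' counts, so the generative synonymous divergence is `ds_true`
#' substitutions per synonymous site.
#'
#' @param n_codons Number of codons.
#' @param ds_true True synonymous divergence (subs per synonymous site).
#' @param omega True dN/dS.
#' @param model A `gtr_model`.
#' @param seed RNG seed.
#' @return A `gene_alignment` with records `anc` and `des`.
#' @export
simulate_divergent_pair <- function(n_codons, ds_true, omega = 0.3,
                                    model = gtr_model(), seed = 1) {
  set.seed(seed)
  tab <- codon_idx_tables()
  anc <- random_coding_seq(n_codons, model$base_freqs)
  cod_anc <- tab$cod[vapply(seq_len(n_codons), function(ci) codon_at(anc, ci),
                            numeric(1))]
  cnt <- ng_tables()
  S0 <- sum(cnt$S[cod_anc]); N0 <- sum(cnt$N[cod_anc])
  n_syn <- rpois(1, ds_true * S0)
  n_non <- rpois(1, omega * ds_true * N0)
  des <- anc
  prow <- -model$Q; diag(prow) <- 0
  prow <- prow / rowSums(prow)
  L <- 3L * n_codons
  done_s <- 0L; done_n <- 0L; guard <- 0L
  while ((done_s < n_syn || done_n < n_non) && guard < 1e7) {
    guard <- guard + 1L
    pos <- sample.int(L, 1)
    b <- des[pos]
    nb <- sample.int(4, 1, prob = prow[b, ])
    ci <- (pos - 1L) %/% 3L + 1L
    old_idx <- codon_at(des, ci)
    tmp <- des[(3 * ci - 2):(3 * ci)]; tmp[pos - 3 * (ci - 1L)] <- nb
    new_idx <- 16 * (tmp[1] - 1) + 4 * (tmp[2] - 1) + tmp[3]
    if (tab$stop[new_idx]) next
    if (tab$aa[old_idx] == tab$aa[new_idx]) {
      if (done_s >= n_syn) next
      des[pos] <- nb; done_s <- done_s + 1L
    } else {
      if (done_n >= n_non) next
      des[pos] <- nb; done_n <- done_n + 1L
    }
  }
  gene_alignment(rbind(anc = int_to_res(anc), des = int_to_res(des)))
}

#' Simulate an edit-site retention tally under a known transfer mechanism
#'
#' The reduced generative model behind the mechanism test: a DNA-mediated
#' transfer leaves `C` at each edit site, flipped to `T` with the background
#' substitution probability; an RNA-mediated transfer (cDNA of an edited
#' transcript) carries `T` at the fully-edited fraction of sites.
#'
#' @param n_sites Number of assessable edit sites.
#' @param mechanism `"DNA"` or `"RNA"`.
#' @param background_c_to_t Background C-to-T probability.
#' @param edited_fraction Fully-edited fraction.
#' @param id Target id recorded in the tally.
#' @return A `retention_tally` (verdict unset).
#' @export
simulate_edit_retention <- function(n_sites, mechanism = c("DNA", "RNA"),
                                    background_c_to_t = 0.02,
                                    edited_fraction = 0.9,
                                    id = "sim_target") {
  mechanism <- match.arg(mechanism)
  isT <- if (mechanism == "DNA") runif(n_sites) < background_c_to_t
  else runif(n_sites) < edited_fraction
  # residual C can still hit background substitution under RNA transfer
  if (mechanism == "RNA") {
    resid <- !isT
    isT[resid] <- runif(sum(resid)) < background_c_to_t
  }
  out <- tibble::tibble(target_id = id, n_sites_assessed = n_sites,
                        n_C = sum(!isT), n_T = sum(isT), n_other = 0L,
                        n_outside_span = 0L,
                        verdict = NA_character_, verdict_p = NA_real_)
  class(out) <- c("retention_tally", class(out))
  out
}

#' Compare pipeline outputs to a simulation truth ledger
#'
#' Computes per-stage recovery metrics for whichever result components are
#' supplied: foreign-copy classification precision/recall, conversion-tract
#' boundary error (columns, against the informative-site-delimited truth),
#' mechanism-call accuracy, and qPCR compartment-call accuracy.
#'
#' @param result List with any of: `foreign_ids` (character, or a data
#'   frame with `gene` and `id`), `tracts` (tibble with `query_id`, `start`,
#'   `end`), `mechanism` (character verdicts, e.g. `"DNA-mediated"`),
#'   `compartment_calls` (tibble `locus_id`, `call`).
#' @param truth The `truth` component of a [simulate_dataset()] result.
#' @param genes Restrict the comparison to these genes (default all).
#' @return A tibble with columns `metric`, `value`, `n`.
#' @export
truth_compare <- function(result, truth, genes = NULL) {
  if (!is.null(genes)) {
    truth$foreign_ids_by_gene <- truth$foreign_ids_by_gene[genes]
    truth$foreign_ids <- unlist(truth$foreign_ids_by_gene, use.names = FALSE)
    if (!is.null(truth$tracts) && nrow(truth$tracts))
      truth$tracts <- truth$tracts[truth$tracts$gene %in% genes, , drop = FALSE]
  }
  rows <- list()
  if (!is.null(result$foreign_ids)) {
    # ids repeat across genes, so compare gene:id pairs when genes are given
    as_keys <- function(x) {
      if (is.data.frame(x)) paste(x$gene, x$id, sep = ":") else unique(x)
    }
    pred <- as_keys(result$foreign_ids)
    act <- if (is.data.frame(result$foreign_ids)) {
      unlist(lapply(names(truth$foreign_ids_by_gene), function(g)
        paste(g, truth$foreign_ids_by_gene[[g]], sep = ":")))
    } else unique(truth$foreign_ids)
    tp <- length(intersect(pred, act))
    prec <- if (length(pred)) tp / length(pred) else NA_real_
    rec <- if (length(act)) tp / length(act) else NA_real_
    rows <- c(rows, list(
      tibble::tibble(metric = "classification_precision", value = prec,
                     n = length(pred)),
      tibble::tibble(metric = "classification_recall", value = rec,
                     n = length(act))))
  }
  if (!is.null(result$tracts) && !is.null(truth$tracts) &&
      nrow(truth$tracts)) {
    errs <- vapply(seq_len(nrow(truth$tracts)), function(i) {
      tt <- truth$tracts[i, ]
      hits <- result$tracts[result$tracts$query_id == tt$query_id, ,
                            drop = FALSE]
      if (!nrow(hits) || is.na(tt$start)) return(NA_real_)
      # nearest detected tract
      d <- pmax(abs(hits$start - tt$start), abs(hits$end - tt$end))
      min(d)
    }, numeric(1))
    rows <- c(rows, list(tibble::tibble(metric = "tract_boundary_error",
                                        value = mean(errs, na.rm = TRUE),
                                        n = sum(!is.na(errs)))))
  }
  if (!is.null(result$mechanism)) {
    expected <- paste0(truth$mechanism, "-mediated")
    acc <- mean(result$mechanism == expected)
    rows <- c(rows, list(tibble::tibble(metric = "mechanism_accuracy",
                                        value = acc,
                                        n = length(result$mechanism))))
  }
  if (!is.null(result$compartment_calls)) {
    cc <- result$compartment_calls
    tc <- truth$qpcr_compartment[cc$locus_id]
    acc <- mean(cc$call == tc)
    rows <- c(rows, list(tibble::tibble(metric = "compartment_accuracy",
                                        value = acc, n = nrow(cc))))
  }
  if (!length(rows)) stop("no comparable result components supplied",
                          call. = FALSE)
  dplyr::bind_rows(rows)
}
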