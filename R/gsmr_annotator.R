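#' Candidate genes for one orphan reaction by domain matching
#'
#' A gene is a candidate when its E-value-filtered domain multiset contains
#' the reaction's required domain multiset with the required multiplicity
#' (a reaction demanding a domain twice is only matched by genes carrying
#' two copies). Candidates carrying additional, unrelated domains are
#' flagged `extra_domains`: such multi-domain genes cannot be unambiguously
#' assigned.
#'
#' @param reaction one-row data.frame with reaction_id, required_domains
#'   (comma-joined multiset), essential
#' @param domain_table data.frame gene_id, domain_id, evalue
#' @param evalue_max E-value cut-off (default 0.001)
#' @return data.frame: gene_id, best_evalue, extra_domains
#' @export
match_domains <- function(reaction, domain_table, evalue_max = 0.001) {
  req <- strsplit(reaction$required_domains[1L], ",")[[1L]]
  req_tab <- table(req)
  dt <- domain_table[domain_table$evalue <= evalue_max, , drop = FALSE]
  out <- list()
  for (gid in unique(dt$gene_id)) {
    gd <- dt[dt$gene_id == gid, , drop = FALSE]
    have <- table(gd$domain_id)
    ok <- all(names(req_tab) %in% names(have)) &&
      all(have[names(req_tab)] >= req_tab)
    if (!ok) next
    extra <- length(setdiff(names(have), names(req_tab))) > 0L
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid,
      best_evalue = min(gd$evalue[gd$domain_id %in% names(req_tab)]),
      extra_domains = extra, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), best_evalue = numeric(),
                      extra_domains = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synteny score of a gene against reference genomes
#'
#' Fraction of the gene's own +/-`k` ortholog-group neighbourhood that is
#' conserved within +/-`k` of the gene's ortholog in a reference genome;
#' the score is the maximum over references (and over paralogous placements
#' within one reference). 1 means the full neighbourhood is conserved
#' somewhere; 0 means no orthologous neighbour is found anywhere.
#'
#' @param gene_id gene in the focal genome
#' @param orthologs data.frame genome, gene, ortho_group, position_index;
#'   the focal genome is `"self"`
#' @param k neighbourhood radius, genes
#' @return numeric in `[0, 1]`
#' @export
synteny_score <- function(gene_id, orthologs, k = 5L) {
  self <- orthologs[orthologs$genome == "self", , drop = FALSE]
  i <- match(gene_id, self$gene)
  if (is.na(i)) stop("gene ", gene_id, " absent from the focal ortholog table")
  my_group <- self$ortho_group[i]
  nb <- unique(self$ortho_group[
    abs(self$position_index - self$position_index[i]) <= k &
      self$gene != gene_id])
  if (length(nb) == 0L) return(0)
  best <- 0
  for (rg in setdiff(unique(orthologs$genome), "self")) {
    ref <- orthologs[orthologs$genome == rg, , drop = FALSE]
    for (a in which(ref$ortho_group == my_group)) {
      near <- abs(ref$position_index - ref$position_index[a]) <= k
      rnb <- ref$ortho_group[near & seq_len(nrow(ref)) != a]
      best <- max(best, sum(nb %in% rnb) / (2 * k))
    }
  }
  min(best, 1)
}

#' Assign candidate genes to orphan reactions
#'
#' For each reaction, candidates from [match_domains] are ranked
#' lexicographically by (domain completeness — all candidates are complete,
#' so effectively) best E-value, then synteny score (descending), then
#' gene id. Verdicts: `unassigned` (no candidate), `single_candidate`,
#' `ambiguous_multidomain` (every candidate carries unrelated extra
#' domains), `multiple_candidates` otherwise. Essential unassigned
#' reactions are flagged prominently in the report.
#'
#' @param reactions data.frame reaction_id, required_domains, essential
#' @param domain_table data.frame gene_id, domain_id, evalue
#' @param ortholog_table see [synteny_score]
#' @param evalue_max E-value cut-off
#' @param k synteny neighbourhood radius
#' @return data.frame: reaction_id, essential, verdict, top_gene,
#'   n_candidates, candidates (list column of ranked candidate
#'   data.frames with domain_score, synteny_score, combined_rank)
#' @export
assign_orphans <- function(reactions, domain_table, ortholog_table,
                           evalue_max = 0.001, k = 5L) {
  rows <- list()
  for (ri in seq_len(nrow(reactions))) {
    rxn <- reactions[ri, , drop = FALSE]
    cand <- match_domains(rxn, domain_table, evalue_max)
    if (nrow(cand) > 0L) {
      cand$domain_score <- 1
      cand$synteny_score <- vapply(cand$gene_id, function(g)
        if (g %in% ortholog_table$gene[ortholog_table$genome == "self"])
          synteny_score(g, ortholog_table, k) else 0, numeric(1))
      o <- order(-cand$domain_score, cand$best_evalue,
                 -cand$synteny_score, cand$gene_id)
      cand <- cand[o, , drop = FALSE]
      cand$combined_rank <- seq_len(nrow(cand))
      rownames(cand) <- NULL
    }
    verdict <- if (nrow(cand) == 0L) "unassigned"
      else if (all(cand$extra_domains)) "ambiguous_multidomain"
      else if (nrow(cand) == 1L) "single_candidate"
      else "multiple_candidates"
    rows[[ri]] <- data.frame(
      reaction_id = rxn$reaction_id, essential = isTRUE(rxn$essential),
      verdict = verdict,
      top_gene = if (verdict %in% c("unassigned", "ambiguous_multidomain"))
        NA_character_ else cand$gene_id[1L],
      n_candidates = nrow(cand), stringsAsFactors = FALSE)
    rows[[ri]]$candidates <- I(list(cand))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Human-readable orphan-assignment report
#' @param assignments output of [assign_orphans]
#' @return character vector of report lines
#' @export
gsmr_report <- function(assignments) {
  lines <- character(0)
  urgent <- assignments$essential & assignments$verdict == "unassigned"
  if (any(urgent))
    lines <- c(lines,
               "!! ESSENTIAL REACTIONS WITHOUT A CANDIDATE GENE:",
               sprintf("!!   %s", assignments$reaction_id[urgent]), "")
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    cand <- a$candidates[[1L]]
    detail <- if (nrow(cand) == 0L) "no gene matches the domain requirements"
      else paste(sprintf("%s (E=%.1e, synteny=%.2f)", cand$gene_id,
                         cand$best_evalue, cand$synteny_score),
                 collapse = "; ")
    lines <- c(lines, sprintf("%s [%s]%s: %s", a$reaction_id, a$verdict,
                              if (a$essential) " (essential)" else "",
                              detail))
  }
  lines
}
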