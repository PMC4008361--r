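#' Merge all evidence streams into an updated annotation
#'
#' Deterministic merge of proteogenomic protein calls, transcribed-region
#' calls, RBS calls and orphan-reaction assignments into the existing
#' annotation, with machine-parsable evidence codes (PEP, TXN, RBS, GSMR)
#' in the attributes. Peptide evidence outranks transcription for gene
#' existence: a transcribed region overlapping a newly added gene on the
#' same strand is not emitted separately. Function reassignments never
#' overwrite a previous product silently — the old value is kept as
#' `previous_product`. Existing genes are never deleted; contradicted
#' models only acquire flags. Integration is idempotent: re-running on its
#' own output with the same evidence yields zero new updates.
#'
#' @param annotation [gene_models] data.frame (the current annotation)
#' @param protein_calls filtered calls from [filter_proteins] (may be NULL)
#' @param transcribed_regions data.frame from [detect_transcribed_regions]
#'   (may be NULL)
#' @param rbs_calls calls data.frame from [call_rbs] (may be NULL)
#' @param orphan_assignments data.frame from [assign_orphans] (may be NULL)
#' @param rbs_attach_dist maximum nt between an RBS window end and the
#'   downstream start codon it annotates
#' @return list(models = updated [gene_models], updates = data.frame of
#'   applied updates, conflicts = data.frame of logged conflicts)
#' @export
integrate_evidence <- function(annotation, protein_calls = NULL,
                               transcribed_regions = NULL,
                               rbs_calls = NULL, orphan_assignments = NULL,
                               rbs_attach_dist = 25L) {
  models <- annotation
  updates <- list(); conflicts <- list()
  upd <- function(action, id, chrom, start, end, strand, evidence, detail) {
    updates[[length(updates) + 1L]] <<- data.frame(
      action = action, target_id = id, chrom = chrom, start = start,
      end = end, strand = strand, evidence = evidence, detail = detail,
      stringsAsFactors = FALSE)
  }
  set_attr <- function(i, key, value) {
    a <- models$attributes[[i]]
    a[key] <- value
    models$attributes[[i]] <<- a
  }
  get_attr <- function(i, key) {
    a <- models$attributes[[i]]
    if (key %in% names(a)) unname(a[[key]]) else NULL
  }
  has_evidence <- function(i, code) {
    ev <- models$attributes[[i]]["evidence"]
    !is.na(ev) && code %in% strsplit(ev, ",")[[1L]]
  }
  add_evidence <- function(i, code) {
    ev <- models$attributes[[i]]["evidence"]
    codes <- if (is.na(ev)) character(0) else strsplit(ev, ",")[[1L]]
    set_attr(i, "evidence", paste(unique(c(codes, code)), collapse = ","))
  }

  # --- proteogenomics -----------------------------------------------------
  if (!is.null(protein_calls) && nrow(protein_calls) > 0L) {
    acc <- protein_calls[protein_calls$status == "accepted", , drop = FALSE]
    for (i in seq_len(nrow(acc))) {
      cl <- acc[i, ]
      ev <- if (isTRUE(cl$rna_validated)) "PEP,TXN" else "PEP"
      if (cl$classification == "novel") {
        dup <- models$chrom == cl$chrom & models$start == cl$start &
          models$end == cl$end & models$strand == cl$strand
        if (any(dup)) {
          j <- which(dup)[1L]
          for (code in strsplit(ev, ",")[[1L]])
            if (!has_evidence(j, code)) add_evidence(j, code)
          next
        }
        opp <- models$kind == "CDS" & models$chrom == cl$chrom &
          models$strand != cl$strand & models$start < cl$end &
          models$end > cl$start
        if (any(opp)) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            type = "antisense_overlap", a = cl$chrom,
            detail = sprintf("novel ORF %d-%d (%s) overlaps %s on the other strand; both kept",
                             cl$start, cl$end, cl$strand,
                             paste(models$gene_id[opp], collapse = ",")),
            stringsAsFactors = FALSE)
        }
        nid <- sprintf("novel_%s_%d_%s", cl$chrom, cl$start, cl$strand)
        nm <- gene_models(nid, cl$chrom, cl$start, cl$end, cl$strand,
                          kind = "CDS",
                          attributes = list(c(
                            evidence = ev, classification = "novel",
                            n_peptides = as.character(cl$n_conf_peptides),
                            product = "novel protein")))
        models <- rbind(models, nm)
        class(models) <- c("gene_models", "data.frame")
        upd("add_gene", nid, cl$chrom, cl$start, cl$end, cl$strand, ev,
            sprintf("%d confident peptides", cl$n_conf_peptides))
      } else if (cl$classification %in% c("confirms_hypothetical",
                                          "extension")) {
        ov <- which(models$kind == "CDS" & models$chrom == cl$chrom &
                      models$strand == cl$strand &
                      models$start < cl$end & models$end > cl$start)
        for (j in ov) {
          if (has_evidence(j, "PEP")) next
          add_evidence(j, "PEP")
          upd("confirm_gene", models$gene_id[j], models$chrom[j],
              models$start[j], models$end[j], models$strand[j], "PEP",
              cl$classification)
        }
      } else if (cl$classification == "frameshift_flag") {
        near <- which(models$kind == "CDS" & models$chrom == cl$chrom &
                        models$strand == cl$strand &
                        models$start < cl$end + 3L &
                        models$end > cl$start - 3L)
        for (j in near) {
          if (!is.null(get_attr(j, "frameshift_suspect"))) next
          set_attr(j, "frameshift_suspect", "true")
          set_attr(j, "frameshift_evidence_orf",
                   sprintf("%d-%d", cl$start, cl$end))
          upd("flag_frameshift", models$gene_id[j], models$chrom[j],
              models$start[j], models$end[j], models$strand[j], "PEP",
              sprintf("peptide ORF %d-%d in shifted frame", cl$start,
                      cl$end))
        }
      }
    }
  }

  # --- transcription ------------------------------------------------------
  if (!is.null(transcribed_regions) && nrow(transcribed_regions) > 0L) {
    for (i in seq_len(nrow(transcribed_regions))) {
      tr <- transcribed_regions[i, ]
      covered <- models$chrom == tr$chrom & models$strand == tr$strand &
        models$start < tr$end & models$end > tr$start
      if (any(covered)) next  # peptide/gene evidence outranks transcription
      tid <- sprintf("txn_%s_%d_%s", tr$chrom, tr$start, tr$strand)
      if (tid %in% models$gene_id) next
      nm <- gene_models(tid, tr$chrom, tr$start, tr$end, tr$strand,
                        kind = "transcribed_region",
                        attributes = list(c(
                          evidence = "TXN",
                          max_expr = sprintf("%.3f", tr$max_expr),
                          dynamic = tolower(as.character(tr$dynamic)))))
      models <- rbind(models, nm)
      class(models) <- c("gene_models", "data.frame")
      upd("add_transcribed_region", tid, tr$chrom, tr$start, tr$end,
          tr$strand, "TXN", sprintf("max_expr %.2f", tr$max_expr))
    }
  }

  # --- RBS ----------------------------------------------------------------
  if (!is.null(rbs_calls) && nrow(rbs_calls) > 0L) {
    for (i in seq_len(nrow(rbs_calls))) {
      rc <- rbs_calls[i, ]
      # nearest downstream start codon within reach, on either strand's
      # transcript orientation
      cds <- models[models$kind == "CDS", , drop = FALSE]
      dplus <- ifelse(cds$strand == "+", cds$start - rc$window_end,
                      rc$window_start - cds$end)
      ok <- which(dplus >= -3L & dplus <= rbs_attach_dist)
      if (length(ok) == 0L) next
      j0 <- ok[which.min(dplus[ok])]
      gid <- cds$gene_id[j0]
      rid <- sprintf("rbs_%s", gid)
      if (rid %in% models$gene_id) next
      nm <- gene_models(rid, rc$chrom %||% models$chrom[1L],
                        rc$window_start, rc$window_end,
                        cds$strand[j0], kind = "RBS",
                        attributes = list(c(
                          evidence = "RBS", gene = gid,
                          peak_offset = as.character(rc$peak_offset),
                          sd_match = tolower(as.character(rc$sd_match)))))
      models <- rbind(models, nm)
      class(models) <- c("gene_models", "data.frame")
      upd("add_rbs", rid, nm$chrom, nm$start, nm$end, nm$strand, "RBS",
          sprintf("gene %s, peak %d nt", gid, rc$peak_offset))
    }
  }

  # --- GSMR ---------------------------------------------------------------
  if (!is.null(orphan_assignments) && nrow(orphan_assignments) > 0L) {
    single <- orphan_assignments[
      orphan_assignments$verdict == "single_candidate", , drop = FALSE]
    for (i in seq_len(nrow(single))) {
      a <- single[i, ]
      j <- which(models$gene_id == a$top_gene)
      if (length(j) != 1L) next
      newprod <- sprintf("enzyme for %s", a$reaction_id)
      if (identical(get_attr(j, "product"), newprod)) next
      old <- get_attr(j, "product")
      if (!is.null(old)) set_attr(j, "previous_product", old)
      set_attr(j, "product", newprod)
      add_evidence(j, "GSMR")
      upd("reassign_function", models$gene_id[j], models$chrom[j],
          models$start[j], models$end[j], models$strand[j], "GSMR",
          sprintf("%s -> %s", old %||% "(none)", newprod))
    }
  }

  updates <- if (length(updates)) do.call(rbind, updates) else
    data.frame(action = character(), target_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), evidence = character(),
               detail = character())
  conflicts <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(type = character(), a = character(), detail = character())
  models <- models[order(models$chrom, models$start, models$end), ]
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  list(models = models, updates = updates, conflicts = conflicts)
}

#' Count integration updates per action and evidence source
#'
#' @param updates updates data.frame from [integrate_evidence]
#' @return list(by_action, by_evidence, total); the two tables are
#'   data.frames with counts
#' @export
summary_report <- function(updates) {
  by_action <- as.data.frame(table(action = updates$action),
                             stringsAsFactors = FALSE)
  names(by_action)[2L] <- "n"
  codes <- unlist(strsplit(updates$evidence, ","))
  by_evidence <- as.data.frame(table(evidence = codes),
                               stringsAsFactors = FALSE)
  names(by_evidence)[2L] <- "n"
  list(by_action = by_action, by_evidence = by_evidence,
       total = nrow(updates))
}

#' Write a summary report as JSON and TSV
#' @param report output of [summary_report]
#' @param json_path,tsv_path output paths (either may be NULL)
#' @return invisibly, the report
#' @export
write_summary_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    df <- rbind(
      data.frame(group = "action", key = report$by_action$action,
                 n = report$by_action$n),
      data.frame(group = "evidence", key = report$by_evidence$evidence,
                 n = report$by_evidence$n))
    write_tsv_table(df, tsv_path)
  }
  invisible(report)
}

#' Run the full pipeline on a simulated dataset
#'
#' simulate -> intergenic ORF scan -> peptide mapping and filtering ->
#' transcription detection -> RBS calling -> orphan assignment ->
#' integration. The single entry point behind the end-to-end CLI.
#'
#' @param config a [simulation_config]
#' @param k transcription fold threshold
#' @param min_conf,min_peptides protein acceptance parameters
#' @return list with the simulated data plus orfs, calls, filtered,
#'   transcribed, rbs, orphans, integration, summary
#' @export
run_pipeline <- function(config = simulation_config(), k = 5,
                         min_conf = 95, min_peptides = 2L) {
  sim <- simulate_dataset(config)
  norm <- normalize_tracks(sim$coverage, sim$annotation)
  intergenic <- extract_intergenic(sim$annotation, sim$genome)
  orfs <- discover_orfs(sim$annotation, sim$genome)
  calls <- proteogenomic_calls(sim$peptides[, c("peptide", "confidence",
                                                "sample")],
                               sim$genome, sim$annotation,
                               min_conf = min_conf)
  filtered <- filter_proteins(calls, norm, sim$annotation,
                              min_conf = min_conf,
                              min_peptides = min_peptides, k = k)
  transcribed <- detect_transcribed_regions(norm, intergenic,
                                            sim$annotation, k = k)
  anchors <- rbind(
    sim$annotation[sim$annotation$kind == "CDS",
                   c("gene_id", "chrom", "start", "end", "strand")],
    data.frame(gene_id = sprintf("orfcall_%d", seq_len(nrow(filtered))),
               chrom = filtered$chrom, start = filtered$start,
               end = filtered$end,
               strand = filtered$strand)[filtered$status == "accepted" &
                                           filtered$classification ==
                                             "novel", , drop = FALSE])
  rbs <- call_rbs(anchors, sim$fragments, sim$genome)
  orphans <- assign_orphans(sim$gsmr$reactions, sim$gsmr$domains,
                            sim$gsmr$orthologs)
  rbs_with_chrom <- rbs$calls
  if (nrow(rbs_with_chrom) > 0L)
    rbs_with_chrom$chrom <- names(sim$genome)[1L]
  integration <- integrate_evidence(sim$annotation, filtered, transcribed,
                                    rbs_with_chrom, orphans)
  c(sim, list(tracks = norm, intergenic = intergenic, orfs = orfs,
              anchors = anchors, calls = calls, filtered = filtered,
              transcribed = transcribed, rbs = rbs, orphans = orphans,
              integration = integration,
              summary = summary_report(integration$updates)))
}
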