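#' Read a genome FASTA file
#'
#' Loads one or more DNA sequences. Sequences are uppercased; `N` is allowed;
#' any non-DNA character (including RNA `U`) is a parse error naming the
#' offending line.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet], one element per record
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgt", "ACGT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1L]], ">"))
    stop("malformed FASTA: line ", nonblank[1L], " is not a '>' header")
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(ln)) < 2L)
        stop("malformed FASTA: empty header at line ", i)
    } else if (grepl("[^ACGTNacgtn]", ln)) {
      stop("malformed FASTA: non-DNA character (alphabet is A/C/G/T/N) ",
           "at line ", i)
    }
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write sequences to FASTA
#' @param seqs named DNAStringSet or named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a gene-model table
#'
#' The central annotation container: one row per feature, coordinates
#' 0-based half-open on the forward strand.
#'
#' @param gene_id,chrom,start,end,strand,kind vectors, recycled to a common
#'   length; `kind` is a feature type such as `"CDS"`, `"rRNA"`, `"tRNA"`,
#'   `"novel_ORF"` or `"RBS"`
#' @param attributes list of named character vectors (free-form key/value
#'   metadata per feature), or `NULL`
#' @param genome optional DNAStringSet used to bounds-check coordinates
#' @return a `data.frame` with class `"gene_models"`
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        kind = "CDS", attributes = NULL, genome = NULL) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   kind = as.character(kind),
                   stringsAsFactors = FALSE)
  if (is.null(attributes)) attributes <- rep(list(character()), nrow(df))
  stopifnot(length(attributes) == nrow(df))
  df$attributes <- I(attributes)
  validate_gene_models(df, genome)
  class(df) <- c("gene_models", "data.frame")
  df
}

validate_gene_models <- function(df, genome = NULL) {
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad))
    stop("invalid gene model coordinates (need 0 <= start < end) for: ",
         paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene model strand must be '+' or '-'")
  if (!is.null(genome)) {
    len <- setNames(Biostrings::width(genome), names(genome))
    over <- which(df$end > len[df$chrom])
    if (length(over))
      stop("gene model beyond genome end: ",
           paste(df$gene_id[over], collapse = ", "))
  }
  cds <- which(df$kind == "CDS")
  broken <- vapply(df$attributes[cds], function(a)
    "broken" %in% names(a), logical(1))
  nd3 <- cds[(df$end[cds] - df$start[cds]) %% 3L != 0L & !broken]
  if (length(nd3))
    stop("CDS length not divisible by 3 (and not flagged broken): ",
         paste(df$gene_id[nd3], collapse = ", "))
  invisible(df)
}

models_to_granges <- function(models) {
  mc <- S4Vectors::DataFrame(
    gene_id = models$gene_id, kind = models$kind)
  GenomicRanges::GRanges(models$chrom,
                         IRanges::IRanges(models$start + 1L, models$end),
                         strand = models$strand, mc)
}

gff3_type_to_kind <- function(type) {
  map <- c(ribosome_binding_site = "RBS")
  ifelse(type %in% names(map), map[type], type)
}
kind_to_gff3_type <- function(kind) {
  map <- c(RBS = "ribosome_binding_site")
  ifelse(kind %in% names(map), map[kind], kind)
}

#' Read a GFF3 annotation
#'
#' Converts the 1-based closed GFF3 coordinates to the internal 0-based
#' half-open convention and preserves all attributes. Records with `end <
#' start` or a strand other than `+`/`-` raise an error naming the line.
#'
#' @param path path to a GFF3 file
#' @param keep_types optional character vector of feature types to keep
#'   (default: all)
#' @return a [gene_models] data.frame
#' @export
read_gff3 <- function(path, keep_types = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e) || e < s)
      stop("malformed GFF3 at line ", i, ": end < start or non-integer bounds")
    if (!f[7L] %in% c("+", "-"))
      stop("malformed GFF3 at line ", i, ": unsupported strand '", f[7L], "'")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(keep_types)) gr <- gr[as.character(gr$type) %in% keep_types]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    paste0("feature_", seq_along(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  skip <- c("source", "type", "score", "phase", "ID")
  extras <- setdiff(names(mc), skip)
  attrs <- lapply(seq_along(gr), function(i) {
    vals <- vapply(extras, function(k) {
      v <- mc[[k]][i]
      if (is.list(v) || methods::is(v, "List")) v <- unlist(v)
      if (length(v) == 0L || all(is.na(v))) NA_character_ else
        paste(as.character(v), collapse = ",")
    }, character(1))
    vals[!is.na(vals)]
  })
  gene_models(gene_id = ids,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)),
              kind = gff3_type_to_kind(as.character(gr$type)),
              attributes = attrs)
}

#' Write gene models to GFF3
#'
#' Emits 1-based closed coordinates; attribute key/value pairs are written as
#' GFF3 column-9 tags.
#'
#' @param models a [gene_models] data.frame
#' @param path output path
#' @param source source tag for column 2
#' @return `path`, invisibly
#' @export
write_gff3 <- function(models, path, source = "annotforge") {
  gr <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand)
  keys <- unique(unlist(lapply(models$attributes, names)))
  mc <- S4Vectors::DataFrame(
    source = source,
    type = kind_to_gff3_type(models$kind),
    ID = models$gene_id,
    phase = ifelse(models$kind == "CDS", 0L, NA_integer_))
  for (k in keys) {
    mc[[k]] <- vapply(models$attributes, function(a)
      if (k %in% names(a)) unname(a[[k]]) else NA_character_, character(1))
  }
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a coverage track
#'
#' @param values non-negative per-base coverage, one value per genome
#'   position
#' @param library_id library identifier
#' @param time_point sample/time-point label
#' @param strand `"+"`, `"-"` or `"both"`
#' @return a `coverage_track` object
#' @export
coverage_track <- function(values, library_id = "lib1",
                           time_point = NA_character_, strand = "both") {
  stopifnot(is.numeric(values), all(values >= 0), !anyNA(values),
            strand %in% c("+", "-", "both"))
  structure(list(library_id = library_id, time_point = time_point,
                 strand = strand, values = as.numeric(values)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track '%s' (time point %s, strand %s): %d bases, mean %.2f\n",
    x$library_id, x$time_point, x$strand, length(x$values), mean(x$values)))
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' bedGraph intervals are 0-based half-open; positions absent from the file
#' read as 0 coverage. Overlapping intervals with conflicting values, and
#' intervals beyond the genome end, are errors.
#'
#' @param path path to a bedGraph file
#' @param genome_length genome length in nt
#' @inheritParams coverage_track
#' @return a [coverage_track]
#' @export
read_bedgraph <- function(path, genome_length, library_id = basename(path),
                          time_point = NA_character_, strand = "both") {
  stopifnot(file.exists(path), genome_length > 0)
  gr <- rtracklayer::import(path, format = "bedGraph")
  st <- GenomicRanges::start(gr) - 1L
  en <- GenomicRanges::end(gr)
  if (any(en > genome_length) || any(st < 0L))
    stop("bedGraph interval out of genome bounds [0, ", genome_length, ")")
  values <- numeric(genome_length)
  o <- order(st)
  st <- st[o]; en <- en[o]; sc <- gr$score[o]
  for (i in seq_along(st)) {
    span <- (st[i] + 1L):en[i]
    prev <- values[span]
    clash <- prev != 0 & prev != sc[i]
    if (any(clash))
      stop("overlapping bedGraph intervals with conflicting values near ",
           "position ", st[i] + which(clash)[1L] - 1L)
    values[span] <- sc[i]
  }
  coverage_track(values, library_id, time_point, strand)
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track]
#' @param chrom chromosome name for column 1
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, chrom, path) {
  r <- rle(track$values)
  en <- cumsum(r$lengths)
  st <- en - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = chrom, start = st[keep], end = en[keep],
                   value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read small-RNA fragment alignments from BED6
#'
#' One row per distinct fragment; the BED score column carries the collapsed
#' duplicate count (a `.` or empty score reads as 1). Fragments outside the
#' 15-50 nt size selection are dropped with a warning.
#'
#' @param path path to a BED6 file
#' @param min_len,max_len retained fragment size range, nt
#' @return a data.frame with columns chrom, start, end, strand, count
#'   (0-based half-open coordinates)
#' @export
read_fragments_bed <- function(path, min_len = 15L, max_len = 50L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      count = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 6L))
    stop("malformed BED6 at line ", which(ncol < 6L)[1L],
         ": expected 6 fields")
  m <- do.call(rbind, f)
  score <- m[, 5L]
  count <- suppressWarnings(as.integer(score))
  count[is.na(count) | count < 1L] <- 1L
  df <- data.frame(chrom = m[, 1L],
                   start = as.integer(m[, 2L]), end = as.integer(m[, 3L]),
                   strand = m[, 6L], count = count,
                   stringsAsFactors = FALSE)
  if (any(df$end <= df$start))
    stop("malformed BED6: end <= start at line ",
         which(df$end <= df$start)[1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("fragment BED requires stranded records ('+'/'-')")
  len <- df$end - df$start
  bad <- len < min_len | len > max_len
  if (any(bad)) {
    warning(sum(bad), " fragment(s) outside the ", min_len, "-", max_len,
            " nt size selection rejected")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write fragments (or any interval table) as BED6
#' @param x data.frame with chrom, start, end, strand and optionally count
#'   (written to the score column) and name columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                   name = if ("name" %in% names(x)) x$name else ".",
                   score = if ("count" %in% names(x)) x$count else 0L,
                   strand = x$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table with a header row
#' @param path path to a TSV file
#' @return data.frame
#' @export
read_tsv_table <- function(path) {
  stopifnot(file.exists(path))
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "")
}

#' Write a tab-delimited table with a header row
#' @param df data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Runs every file through the matching reader and collects pass/fail
#' verdicts; the backend of the `annotforge validate` command.
#'
#' @param paths named character vector; names give the format
#'   (`fasta`, `gff3`, `bedgraph`, `bed`, `tsv`), values the paths
#' @param genome_length genome length needed to check bedGraph bounds
#' @return data.frame with columns path, format, ok, message
#' @export
validate_inputs <- function(paths, genome_length = NULL) {
  res <- lapply(seq_along(paths), function(i) {
    fmt <- names(paths)[i]; p <- paths[[i]]
    msg <- "ok"
    ok <- tryCatch({
      switch(fmt,
             fasta = read_fasta(p),
             gff3 = read_gff3(p),
             bedgraph = read_bedgraph(p, genome_length %||%
                                        stop("genome_length required")),
             bed = read_fragments_bed(p),
             tsv = read_tsv_table(p),
             stop("unknown format '", fmt, "'"))
      TRUE
    }, error = function(e) { msg <<- conditionMessage(e); FALSE },
       warning = function(w) { msg <<- conditionMessage(w); TRUE })
    data.frame(path = p, format = fmt, ok = ok, message = msg)
  })
  do.call(rbind, res)
}
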