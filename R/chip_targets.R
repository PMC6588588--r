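#' Read ChIP-seq peaks (narrowPeak or BED)
#'
#' Coordinates are kept in the native BED convention, 0-based half-open.
#' For 10-column ENCODE narrowPeak the `score` is taken from the
#' signalValue column (7); for plain BED it is column 5 when present,
#' otherwise `NA`.
#'
#' @param path Peak file.
#' @param format `"narrowPeak"` or `"bed"`; inferred from the extension by
#'   default.
#' @param idr_class Label recorded on every peak, one of `"conservative"`,
#'   `"optimal"`, `"both"`, `"none"`. ENCODE publishes conservative and
#'   optimal IDR-thresholded sets as separate files, so the class is a
#'   property of the file, not recomputed here.
#' @return Tibble with columns `chrom`, `start`, `end`, `score`,
#'   `idr_class`.
#' @export
read_peaks <- function(path, format = NULL,
                       idr_class = c("none", "conservative", "optimal",
                                     "both")) {
  idr_class <- match.arg(idr_class)
  if (!file.exists(path)) {
    pd_abort(sprintf("peak file not found: %s", path), "pd_io_error")
  }
  format <- format %||%
    (if (grepl("narrowpeak$", path, ignore.case = TRUE)) "narrowPeak"
     else "bed")
  format <- match.arg(format, c("narrowPeak", "bed"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    warn(sprintf("no peak records in %s", path))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  score = numeric(), idr_class = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- map_int(fields, length)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    pd_abort(sprintf("peak record with < 3 columns at line %d: %s",
                     i, lines[i]), "pd_parse_error")
  }
  chrom <- map_chr(fields, 1)
  start <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    pd_abort(sprintf("invalid peak interval (start >= end or non-numeric) at line %d: %s",
                     bad[1], lines[bad[1]]), "pd_parse_error")
  }
  score <- if (format == "narrowPeak") {
    ifelse(nf >= 7, suppressWarnings(as.numeric(map_chr(fields, function(f)
      if (length(f) >= 7) f[7] else NA_character_))), NA_real_)
  } else {
    ifelse(nf >= 5, suppressWarnings(as.numeric(map_chr(fields, function(f)
      if (length(f) >= 5) f[5] else NA_character_))), NA_real_)
  }
  tibble(chrom = chrom, start = start, end = end, score = score,
         idr_class = idr_class)
}

#' Read transcription start sites (BED or GTF)
#'
#' BED input carries one TSS per row: `chrom`, `start` (0-based TSS
#' position), `end`, gene symbol in column 4, strand in column 6. GTF input
#' is parsed with `rtracklayer`; for every `transcript` feature the TSS is
#' the feature start on the + strand and the feature end on the - strand,
#' converted to 0-based, and records are collapsed to unique (gene, tss)
#' pairs.
#'
#' @param path TSS file.
#' @param format `"bed"` or `"gtf"`; inferred from the extension by default.
#' @return Tibble with columns `gene`, `chrom`, `tss` (0-based), `strand`.
#' @export
read_tss <- function(path, format = NULL) {
  if (!file.exists(path)) {
    pd_abort(sprintf("TSS file not found: %s", path), "pd_io_error")
  }
  format <- format %||%
    (if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
     else "bed")
  format <- match.arg(format, c("bed", "gtf"))
  out <- if (format == "bed") read_tss_bed(path) else read_tss_gtf(path)
  if (any(!out$strand %in% c("+", "-"))) {
    pd_abort("TSS records must have strand + or -", "pd_parse_error")
  }
  distinct(out, .data$gene, .data$tss, .keep_all = TRUE)
}

read_tss_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- map_int(fields, length)
  if (any(nf < 6)) {
    i <- which(nf < 6)[1]
    pd_abort(sprintf("TSS BED needs 6 columns (gene in 4, strand in 6); line %d",
                     i), "pd_parse_error")
  }
  tibble(gene = map_chr(fields, 4),
         chrom = map_chr(fields, 1),
         tss = as.integer(map_chr(fields, 2)),
         strand = map_chr(fields, 6))
}

read_tss_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    pd_abort("GTF input needs the rtracklayer package", "pd_io_error")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == "transcript"]
  if (length(gr) == 0) {
    pd_abort("no transcript features in GTF", "pd_parse_error")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    pd_abort("GTF transcript without strand", "pd_parse_error")
  }
  gene <- gr$gene_name
  if (is.null(gene)) gene <- gr$gene_id
  # GTF is 1-based inclusive; 0-based TSS = start-1 (+) or end-1 (-)
  tibble(gene = as.character(gene),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         tss = ifelse(strand == "+",
                      GenomicRanges::start(gr) - 1L,
                      GenomicRanges::end(gr) - 1L),
         strand = strand)
}

#' Candidate gene sets
#'
#' Lightweight container recording a gene set together with its provenance
#' (`"pdtg"` for ChIP-derived direct candidates, `"ptg"` once indirect
#' targets are merged in) and the mapping parameters used to build it.
#'
#' @param genes Character vector of gene symbols.
#' @param provenance `"pdtg"` or `"ptg"`.
#' @param parameters Named list (window, mode, idr mode, ...).
#' @return A `pd_gene_set`.
#' @export
gene_set <- function(genes, provenance = c("pdtg", "ptg"),
                     parameters = list()) {
  provenance <- match.arg(provenance)
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  structure(list(genes = sort(genes), provenance = provenance,
                 parameters = parameters),
            class = "pd_gene_set")
}

#' @export
print.pd_gene_set <- function(x, ...) {
  cat(sprintf("<gene set> %d genes (%s)\n", length(x$genes), x$provenance))
  if (length(x$parameters) > 0) {
    cat("  ", paste(names(x$parameters), unlist(x$parameters),
                    sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Map peaks to candidate target genes by TSS proximity
#'
#' A gene is a candidate iff the midpoint of at least one peak lies within
#' the window around one of its TSSs. With `mode = "upstream"` the window is
#' strand-aware: `[tss - window, tss)` on the + strand and
#' `(tss, tss + window]` on the - strand. With `mode = "both"` it is the
#' symmetric `[tss - window, tss + window]`. The default 2000 bp upstream
#' window reflects the promoter-proximal binding expected of direct TF
#' targets; widen the window (or switch mode) to trade specificity for
#' candidate-set size.
#'
#' @param peaks Tibble from [read_peaks()].
#' @param tss Tibble from [read_tss()].
#' @param window Half-width in bp (> 0), default 2000.
#' @param mode `"upstream"` (default) or `"both"`.
#' @return A `pd_gene_set` with provenance `"pdtg"`.
#' @export
map_peaks_to_genes <- function(peaks, tss, window = 2000,
                               mode = c("upstream", "both")) {
  mode <- match.arg(mode)
  if (!is.numeric(window) || window <= 0) {
    pd_abort("`window` must be > 0", "pd_threshold_error")
  }
  if (nrow(tss) == 0) {
    pd_abort("empty TSS table", "pd_input_error")
  }
  if (nrow(peaks) == 0) {
    return(gene_set(character(), "pdtg",
                    list(window = window, mode = mode)))
  }
  mids <- mutate(peaks, mid = floor((.data$start + .data$end) / 2))
  hits <- inner_join(mids, tss, by = "chrom", relationship = "many-to-many")
  hits <- if (mode == "upstream") {
    filter(hits,
           (.data$strand == "+" & .data$mid >= .data$tss - window &
              .data$mid < .data$tss) |
             (.data$strand == "-" & .data$mid > .data$tss &
                .data$mid <= .data$tss + window))
  } else {
    filter(hits, abs(.data$mid - .data$tss) <= window)
  }
  gene_set(unique(hits$gene), "pdtg",
           list(window = window, mode = mode))
}

#' Combine conservative and optimal IDR candidate sets
#'
#' ENCODE publishes two IDR-thresholded peak sets per experiment; candidate
#' gene sets derived from each are combined by set algebra. Intersection
#' (the default) keeps only genes supported by both, the stringent choice.
#'
#' @param conservative,optimal `pd_gene_set`s or character vectors.
#' @param mode One of `"intersect"`, `"union"`, `"conservative_only"`,
#'   `"optimal_only"`.
#' @return A `pd_gene_set` with provenance `"pdtg"`.
#' @export
combine_idr_sets <- function(conservative, optimal,
                             mode = c("intersect", "union",
                                      "conservative_only", "optimal_only")) {
  mode <- match.arg(mode)
  cg <- if (inherits(conservative, "pd_gene_set")) conservative$genes else
    as.character(conservative)
  og <- if (inherits(optimal, "pd_gene_set")) optimal$genes else
    as.character(optimal)
  genes <- switch(mode,
                  intersect = intersect(cg, og),
                  union = union(cg, og),
                  conservative_only = cg,
                  optimal_only = og)
  if (length(genes) == 0) {
    warn("IDR combination produced an empty candidate set")
  }
  gene_set(genes, "pdtg", list(idr = mode))
}

#' Augment direct candidates with indirect targets
#'
#' Adds literature-derived (or otherwise known) indirect targets to the
#' ChIP-derived candidate set, promoting its provenance from PDTG to PTG.
#'
#' @param pdtg A `pd_gene_set` (or character vector).
#' @param indirect Character vector of genes to add (may be empty).
#' @return A `pd_gene_set` with provenance `"ptg"`.
#' @export
augment_with_indirect <- function(pdtg, indirect = character()) {
  base <- if (inherits(pdtg, "pd_gene_set")) pdtg$genes else
    as.character(pdtg)
  params <- if (inherits(pdtg, "pd_gene_set")) pdtg$parameters else list()
  params$n_indirect <- length(setdiff(indirect, base))
  gene_set(union(base, as.character(indirect)), "ptg", params)
}

#' Write / read a gene-set file
#'
#' One symbol per line, with a header comment recording provenance and
#' parameters.
#'
#' @param x A `pd_gene_set`.
#' @param path Output / input file.
#' @return `path` invisibly; `read_gene_set()` returns a `pd_gene_set`.
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "pd_gene_set"))
  hdr <- sprintf("# provenance=%s %s", x$provenance,
                 paste(names(x$parameters), unlist(x$parameters),
                       sep = "=", collapse = " "))
  writeLines(c(hdr, x$genes), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prov <- "ptg"
  m <- regmatches(lines[1], regexec("provenance=(\\w+)", lines[1]))[[1]]
  if (length(m) == 2) prov <- m[2]
  genes <- lines[!startsWith(lines, "#")]
  gene_set(genes[nzchar(genes)], provenance = prov)
}
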