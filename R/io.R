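#' @importFrom GenomicRanges GRanges seqnames start end strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table
NULL

#' Default mapping from annotation biotype strings to the internal vocabulary
#'
#' GENCODE-style `gene_type` values are collapsed onto the four feature
#' classes the pipeline distinguishes: `lncRNA`, `PCG` (protein-coding
#' gene), `TF` (transcription factor, a protein-coding gene with targets in
#' the TF-gene table) and `miRNA`. Releases differ in their lncRNA
#' vocabulary, so the map accepts the common historical subtypes.
#'
#' @return named character vector: annotation value -> internal biotype.
#' @export
defaultBiotypeMap <- function() {
  c(lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    processed_transcript = "lncRNA", sense_intronic = "lncRNA",
    sense_overlapping = "lncRNA",
    protein_coding = "PCG", PCG = "PCG",
    TF = "TF", miRNA = "miRNA")
}

#' Read a gene annotation as a GRanges
#'
#' Accepts BED6 (0-based half-open; optional 7th column `biotype`) or GTF
#' (1-based closed, GENCODE attribute style `gene_id`/`gene_name`/
#' `gene_type`; only `gene` features are used when a `type` column is
#' present). Coordinates are converted by rtracklayer to the 1-based
#' closed GRanges convention used internally; conversion back happens only
#' on export.
#'
#' The returned GRanges carries metadata columns `gene_id`, `symbol`,
#' `biotype` and `tss` (transcription start site: start on `+`, end on
#' `-`). Records whose biotype is absent from `biotypeMap` are skipped
#' with a single warning giving the count.
#'
#' @param path file path.
#' @param dialect `"BED"` or `"GTF"`.
#' @param biotypeMap named character vector mapping annotation biotype
#'   strings to `lncRNA`/`PCG`/`TF`/`miRNA`; see [defaultBiotypeMap()].
#' @return GRanges, one row per gene, unique `gene_id`.
#' @export
readAnnotation <- function(path, dialect = c("GTF", "BED"),
                           biotypeMap = defaultBiotypeMap()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "BED") {
    extra <- .bedHasBiotype(path)
    gr <- if (extra) {
      rtracklayer::import(path, format = "BED",
                          extraCols = c(biotype = "character"))
    } else rtracklayer::import(path, format = "BED")
    gid <- mcols(gr)$name
    sym <- gid
    bt <- if (extra) mcols(gr)$biotype else rep(NA_character_, length(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GTF")
    if ("type" %in% colnames(mcols(gr)) && any(mcols(gr)$type == "gene"))
      gr <- gr[mcols(gr)$type == "gene"]
    gid <- mcols(gr)$gene_id
    sym <- mcols(gr)$gene_name
    if (is.null(sym)) sym <- gid
    bt <- mcols(gr)$gene_type
    if (is.null(bt)) bt <- rep(NA_character_, length(gr))
  }
  mapped <- unname(biotypeMap[bt])
  drop <- is.na(mapped)
  if (any(drop))
    warning(sum(drop), " record(s) with unknown biotype skipped")
  gr <- gr[!drop]
  ann <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  mcols(ann)$gene_id <- gid[!drop]
  mcols(ann)$symbol <- sym[!drop]
  mcols(ann)$biotype <- mapped[!drop]
  if (anyDuplicated(mcols(ann)$gene_id))
    stop("duplicate gene_id values in annotation")
  mcols(ann)$tss <- ifelse(as.character(strand(ann)) == "-",
                           end(ann), start(ann))
  names(ann) <- mcols(ann)$gene_id
  ann
}

.bedHasBiotype <- function(path) {
  first <- readLines(path, n = 1L)
  length(first) == 1L && length(strsplit(first, "\t")[[1]]) >= 7L
}

#' Write a gene annotation
#'
#' GTF export writes GENCODE-style `gene` features with `gene_id`,
#' `gene_name` and `gene_type` attributes; BED export writes BED6 plus a
#' `biotype` column. Either output round-trips through
#' [readAnnotation()].
#'
#' @param ann GRanges from [readAnnotation()] or [generateCohort()].
#' @param path output file.
#' @param dialect `"GTF"` or `"BED"`.
#' @export
writeAnnotation <- function(ann, path, dialect = c("GTF", "BED")) {
  dialect <- match.arg(dialect)
  if (dialect == "GTF") {
    gr <- GRanges(seqnames(ann), IRanges(start(ann), end(ann)),
                  strand = strand(ann))
    mcols(gr)$source <- "lncSCNA"
    mcols(gr)$type <- "gene"
    mcols(gr)$gene_id <- mcols(ann)$gene_id
    mcols(gr)$gene_name <- mcols(ann)$symbol
    mcols(gr)$gene_type <- mcols(ann)$biotype
    rtracklayer::export(gr, path, format = "GTF")
  } else {
    df <- data.frame(
      chrom = as.character(seqnames(ann)),
      start = start(ann) - 1L,          # BED is 0-based half-open
      end = end(ann),
      name = mcols(ann)$gene_id,
      score = 0L,
      strand = as.character(strand(ann)),
      biotype = mcols(ann)$biotype
    )
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene x sample TSV matrix as an OmicsMatrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Empty cells and `NA` become missing values, never zero. Role
#' invariants (beta range, discrete copy-number codes) are validated on
#' load.
#'
#' @param path TSV file.
#' @param role assay role, see [OmicsMatrix()].
#' @param classMap named character vector mapping sample id -> class
#'   (`"tumor"`/`"normal"`).
#' @return An [OmicsMatrix-class].
#' @export
readMatrix <- function(path, role, classMap) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in matrix file: ", path)
  rownames(m) <- df[[1]]
  missing <- setdiff(colnames(m), names(classMap))
  if (length(missing))
    stop("samples absent from classMap: ", paste(missing, collapse = ", "))
  OmicsMatrix(m, classMap[colnames(m)], role)
}

#' Write an OmicsMatrix as a gene x sample TSV
#'
#' @param m an OmicsMatrix.
#' @param path output TSV; first column `gene_id`, then one column per
#'   sample. Missing values are written as empty cells.
#' @export
writeMatrix <- function(m, path) {
  v <- omicsValues(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read an interaction table
#'
#' TSV with columns `source_id`, `target_id` and optionally `effect`
#' (drug-miRNA tables: `"up"`/`"down"`). Duplicate (source, target) rows
#' are dropped.
#'
#' @param path TSV file.
#' @param kind one of `"miRNA-lncRNA"`, `"miRNA-mRNA"`, `"TF-gene"`,
#'   `"drug-miRNA"`.
#' @return data.frame with columns source_id, target_id, kind
#'   (and effect for drug-miRNA).
#' @export
readInteractions <- function(path,
    kind = c("miRNA-lncRNA", "miRNA-mRNA", "TF-gene", "drug-miRNA")) {
  kind <- match.arg(kind)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_id", "target_id")
  if (!all(need %in% colnames(df)))
    stop("interaction table must have source_id and target_id columns")
  df <- df[!duplicated(df[, need]), , drop = FALSE]
  df$kind <- kind
  rownames(df) <- NULL
  df
}

#' Write an interaction table
#' @param df data.frame with source_id/target_id (+ effect) columns.
#' @param path output TSV.
#' @export
writeInteractions <- function(df, path) {
  keep <- intersect(c("source_id", "target_id", "effect"), colnames(df))
  write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table
#'
#' TSV with columns `sample_id`, `time` (days, > 0) and `event`
#' (0/1 or FALSE/TRUE; 1 = death observed).
#'
#' @param path TSV file.
#' @return data.frame(sample_id, time, event) with logical event.
#' @export
readClinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have sample_id, time, event columns")
  if (any(df$time <= 0)) stop("clinical times must be > 0")
  df$event <- as.logical(df$event)
  df[, need]
}

#' Write a clinical survival table
#' @param df data.frame(sample_id, time, event).
#' @param path output TSV.
#' @export
writeClinical <- function(df, path) {
  out <- df
  out$event <- as.integer(out$event)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a typed network edge table
#'
#' Generic TSV edge-list writer used for co-expression edges, cis pairs,
#' trans triples and ceRNA edges (the latter carry the x/M/L/N/p/q
#' columns of the shared-miRNA test). A zero-row data.frame produces a
#' header-only file; `readEdges(writeEdges(x))` returns an identical
#' table.
#'
#' @param edges data.frame of edges.
#' @param path output TSV.
#' @return `writeEdges`: the path, invisibly. `readEdges`: the
#'   data.frame.
#' @export
writeEdges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeEdges
#' @export
readEdges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a focal-fragment table
#'
#' TSV with columns `fragment_id`, `chrom`, `start`, `end` (1-based
#' closed, as written by [writeFragments()]) and `direction`
#' (`"gain"`/`"loss"`).
#'
#' @param path TSV file.
#' @return GRanges with mcols fragment_id, direction.
#' @export
readFragments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$fragment_id <- df$fragment_id
  mcols(gr)$direction <- df$direction
  names(gr) <- df$fragment_id
  gr
}

#' Write a focal-fragment table
#' @param fragments GRanges with fragment_id/direction mcols.
#' @param path output TSV.
#' @export
writeFragments <- function(fragments, path) {
  df <- data.frame(
    fragment_id = mcols(fragments)$fragment_id,
    chrom = as.character(seqnames(fragments)),
    start = start(fragments), end = end(fragments),
    direction = mcols(fragments)$direction
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GO annotation table
#'
#' TSV with columns `gene_id`, `term_id`, `term_name`.
#' @param path TSV file.
#' @return data.frame(gene_id, term_id, term_name).
#' @export
readGoTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% colnames(df)))
    stop("GO table must have gene_id, term_id, term_name columns")
  df[, need]
}
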