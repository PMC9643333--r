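#' Read motifs from a JASPAR-format text file
#'
#' Parses JASPAR 2016 multi-motif text: each motif is a header line
#' \code{">ID NAME"} followed by four rows \code{A [ n1 n2 ... ]} ...
#' \code{T [ ... ]} in alphabet order. Both counts and probabilities are
#' accepted; each column is normalised to probabilities (zero-sum columns are
#' rejected).
#'
#' @param path path to the file.
#' @param source provenance tag for the parsed motifs: \code{"known"}
#'   (default) or \code{"predicted"}.
#' @return list of [MotifMatrix-class], in file order. TF names are taken from
#'   the header name field, split on \code{"::"} (dimer notation).
#' @examples
#' f <- tempfile(fileext = ".jaspar")
#' writeLines(c(">M1 TFX", "A [ 4 0 0 0 ]", "C [ 0 4 0 0 ]",
#'              "G [ 0 0 4 0 ]", "T [ 0 0 0 4 ]"), f)
#' lib <- readJaspar(f)
#' motifProfile(lib[[1]])
#' @export
readJaspar <- function(path, source = c("known", "predicted")) {
  source <- match.arg(source)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop(sprintf("%s: no '>' motif headers found", path), call. = FALSE)
  }
  out <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- lines[hdr[i]]
    fields <- strsplit(sub("^>\\s*", "", h), "\\s+")[[1]]
    id <- fields[1]
    nm <- if (length(fields) > 1L) paste(fields[-1], collapse = " ") else ""
    block <- lines[(hdr[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (length(block) != 4L)
      stop(sprintf("%s: motif '%s' (line %d): expected 4 matrix rows, found %d",
                   path, id, hdr[i], length(block)), call. = FALSE)
    rows <- vector("list", 4L)
    for (j in 1:4) {
      ln <- trimws(block[j])
      base <- toupper(substr(ln, 1L, 1L))
      if (base != DNA_BASES[j])
        stop(sprintf("%s: motif '%s': row %d should start with '%s', got '%s' (line %d)",
                     path, id, j, DNA_BASES[j], base, hdr[i] + j), call. = FALSE)
      body <- gsub("[][]", " ", substr(ln, 2L, nchar(ln)))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
      if (anyNA(vals))
        stop(sprintf("%s: motif '%s': non-numeric entry in row '%s' (line %d)",
                     path, id, DNA_BASES[j], hdr[i] + j), call. = FALSE)
      rows[[j]] <- vals
    }
    w <- lengths(rows)
    if (length(unique(w)) != 1L)
      stop(sprintf("%s: motif '%s': rows have unequal lengths (%s)",
                   path, id, paste(w, collapse = ",")), call. = FALSE)
    mat <- do.call(rbind, rows)
    rownames(mat) <- DNA_BASES
    tfn <- if (nzchar(nm)) strsplit(nm, "::", fixed = TRUE)[[1]] else character()
    out[[i]] <- MotifMatrix(id, mat, tfNames = tfn, source = source)
  }
  out
}

#' Write motifs to a JASPAR-format text file
#'
#' @param motifs list of [MotifMatrix-class].
#' @param path output path.
#' @param digits significant digits for probabilities (default 10, enough for
#'   1e-9 round-trip fidelity).
#' @return `path`, invisibly.
#' @export
writeJaspar <- function(motifs, path, digits = 10L) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in motifs) {
    nm <- paste(tfNames(m), collapse = "::")
    writeLines(sprintf(">%s%s", motifID(m), if (nzchar(nm)) paste0(" ", nm) else ""), con)
    p <- motifProfile(m)
    for (j in 1:4)
      writeLines(sprintf("%s [ %s ]", DNA_BASES[j],
                         paste(formatC(p[j, ], digits = digits, format = "g"),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read ChIP-seq peaks from a BED file
#'
#' Reads BED3+ (tab-separated, 0-based half-open). Coordinates are converted
#' to the 1-based closed convention of \code{GRanges}; [writePeaksBed()]
#' converts back, so file round-trips are exact.
#'
#' @param path BED file path.
#' @param cellLine cell-line label attached to every peak.
#' @param chromSizes optional named vector of chromosome lengths; when given,
#'   peaks ending beyond the chromosome are rejected.
#' @return a \code{GRanges} with metadata columns \code{cell_line} and
#'   \code{peak_id} (column 4 when present, otherwise
#'   \code{<cellLine>_peak<i>}).
#' @export
readPeaksBed <- function(path, cellLine, chromSizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "", blank.lines.skip = TRUE)
  if (ncol(df) < 3L)
    stop(sprintf("%s: BED requires >= 3 columns", path), call. = FALSE)
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("%s: non-numeric coordinate (first bad line %d)", path,
                 which(is.na(start) | is.na(end))[1]), call. = FALSE)
  if (any(start < 0))
    stop(sprintf("%s: negative start (line %d)", path, which(start < 0)[1]),
         call. = FALSE)
  if (any(start >= end))
    stop(sprintf("%s: start >= end (line %d)", path, which(start >= end)[1]),
         call. = FALSE)
  if (!is.null(chromSizes)) {
    lim <- chromSizes[df[[1]]]
    bad <- which(is.na(lim) | end > lim)
    if (length(bad))
      stop(sprintf("%s: line %d: peak exceeds chromosome bounds", path, bad[1]),
           call. = FALSE)
  }
  ids <- if (ncol(df) >= 4L) df[[4]] else sprintf("%s_peak%d", cellLine, seq_along(start))
  GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = start + 1, end = end),
    cell_line = cellLine, peak_id = ids)
}

#' Write peaks to BED (0-based half-open)
#'
#' @param peaks a \code{GRanges} with a \code{peak_id} metadata column
#'   (optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(peaks, path) {
  ids <- if ("peak_id" %in% names(S4Vectors::mcols(peaks)))
    peaks$peak_id else sprintf("peak%d", seq_along(peaks))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   name = ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motif modules from TSV
#'
#' The module file dialect is: four tab-separated columns
#' \code{module_id}, \code{cell_line}, \code{support},
#' \code{motif_ids} (comma-joined). A module must have at least two distinct
#' member motifs and support >= 1.
#'
#' @param path TSV path (no header).
#' @return data.frame with columns \code{module_id}, \code{cell_line},
#'   \code{support} (integer) and list-column \code{motif_ids}.
#' @export
readMotifModules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(module_id = character(), cell_line = character(),
                      support = integer(),
                      motif_ids = I(list()), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected 4 tab-separated fields", path, bad[1]),
         call. = FALSE)
  support <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(support) || any(support < 1L))
    stop(sprintf("%s: invalid support value (line %d)", path,
                 which(is.na(support) | support < 1L)[1]), call. = FALSE)
  ids <- strsplit(vapply(parts, `[`, "", 4L), ",", fixed = TRUE)
  for (i in seq_along(ids)) {
    if (anyDuplicated(ids[[i]]))
      stop(sprintf("%s: line %d: duplicate motif id within module '%s'",
                   path, i, parts[[i]][1]), call. = FALSE)
    if (length(ids[[i]]) < 2L)
      stop(sprintf("%s: line %d: module '%s' has fewer than 2 motifs",
                   path, i, parts[[i]][1]), call. = FALSE)
  }
  data.frame(module_id = vapply(parts, `[`, "", 1L),
             cell_line = vapply(parts, `[`, "", 2L),
             support = support,
             motif_ids = I(ids), stringsAsFactors = FALSE)
}

#' Write motif modules to TSV
#' @param modules module data.frame as returned by [readMotifModules()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifModules <- function(modules, path) {
  writeLines(sprintf("%s\t%s\t%d\t%s", modules$module_id, modules$cell_line,
                     modules$support,
                     vapply(modules$motif_ids, paste, "", collapse = ",")),
             path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' TSV with four columns: \code{protein_a}, \code{protein_b}, \code{is_tf_a},
#' \code{is_tf_b} (0/1). Edges are deduplicated as unordered pairs;
#' self-edges are dropped with a warning.
#'
#' @param path TSV path (no header).
#' @return a [PPINetwork-class].
#' @export
readPpiEdges <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 4L)
    stop(sprintf("%s: edge list requires 4 columns (a, b, is_tf_a, is_tf_b)", path),
         call. = FALSE)
  fa <- as.integer(df[[3]]); fb <- as.integer(df[[4]])
  if (anyNA(fa) || anyNA(fb) || !all(c(fa, fb) %in% 0:1))
    stop(sprintf("%s: TF flags must be 0/1", path), call. = FALSE)
  flags <- c(setNames(fa == 1L, df[[1]]), setNames(fb == 1L, df[[2]]))
  flags <- flags[!duplicated(names(flags))]
  PPINetwork(df[[1]], df[[2]], flags)
}

#' Write a PPI network to edge-list TSV
#' @param ppi a [PPINetwork-class].
#' @param path output path. Isolated proteins (no edges) are appended as
#'   self-describing flag rows only if they have edges; the file format keeps
#'   edge rows only, so isolated proteins are not round-tripped.
#' @return `path`, invisibly.
#' @export
writePpiEdges <- function(ppi, path) {
  e <- ppiEdges(ppi); f <- ppiTfFlags(ppi)
  writeLines(sprintf("%s\t%s\t%d\t%d", e$a, e$b,
                     as.integer(f[e$a]), as.integer(f[e$b])), path)
  invisible(path)
}

#' Read gene TSS annotation
#'
#' TSV with four columns: \code{gene_id}, \code{chrom}, \code{tss} (0-based
#' position), \code{strand} (+/-). One TSS per gene.
#'
#' @param path TSV path (no header).
#' @return data.frame with those columns.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "character"), quote = "")
  names(df) <- c("gene_id", "chrom", "tss", "strand")
  if (any(df$tss < 0) || any(df$tss != round(df$tss)))
    stop(sprintf("%s: TSS must be non-negative integers", path), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be + or -", path), call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop(sprintf("%s: duplicate gene_id (one TSS per gene)", path), call. = FALSE)
  df$tss <- as.integer(df$tss)
  df
}

#' Write gene TSS annotation to TSV
#' @param annotation annotation data.frame ([readGeneAnnotation()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  writeLines(sprintf("%s\t%s\t%d\t%s", annotation$gene_id, annotation$chrom,
                     annotation$tss, annotation$strand), path)
  invisible(path)
}

#' Read / write a gene-to-GO-term map (TSV: gene_id, term_id)
#' @param path TSV path.
#' @return data.frame with columns \code{gene_id}, \code{term_id}.
#' @export
readGeneGo <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) != 2L)
    stop(sprintf("%s: gene-GO map requires 2 columns", path), call. = FALSE)
  names(df) <- c("gene_id", "term_id")
  df
}

#' @rdname readGeneGo
#' @param gene2go data.frame with columns \code{gene_id}, \code{term_id}.
#' @export
writeGeneGo <- function(gene2go, path) {
  writeLines(sprintf("%s\t%s", gene2go$gene_id, gene2go$term_id), path)
  invisible(path)
}
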