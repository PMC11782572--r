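# Sequence and annotation IO; Voss indicator mapping -----------------------

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read a FASTA file
#'
#' Tolerant of line wrapping and CRLF endings; sequences are uppercased and
#' returned in file order. Structural problems (text before the first
#' header, a header with no sequence) are reported with the offending line
#' number.
#'
#' @param path path to a FASTA file.
#' @return named list of sequences (character strings); names are the
#'   header tokens up to the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    stop(sprintf("FASTA parse error at line 1: empty file %s", path),
         call. = FALSE)
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header",
                 nonblank[1]), call. = FALSE)
  }
  headers <- which(startsWith(lines, ">"))
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  ids <- character(length(headers))
  for (i in seq_along(headers)) {
    h <- headers[i]
    id <- sub("^>\\s*", "", lines[h])
    id <- sub("\\s.*$", "", id)
    if (!nzchar(id)) {
      stop(sprintf("FASTA parse error at line %d: empty header", h),
           call. = FALSE)
    }
    body <- lines[seq.int(h + 1L, bounds[i + 1L] - 1L)][
      seq_len(max(0L, bounds[i + 1L] - h - 1L))]
    seq <- toupper(paste(trimws(body), collapse = ""))
    if (!nzchar(seq)) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                   h, id), call. = FALSE)
    }
    ids[i] <- id
    out[[i]] <- seq
  }
  names(out) <- ids
  out
}

#' Read exon annotations from 3-column BED
#'
#' Intervals are 0-based half-open. Per sequence, intervals are sorted by
#' start and overlapping or bookended intervals are merged with a warning.
#' Intervals outside the sequence bounds are an error naming the record.
#'
#' @param path path to a BED file (chrom, start, end).
#' @param sequence_lengths named integer vector of sequence lengths.
#' @return named list mapping sequence id to an integer matrix with columns
#'   `start`, `end`.
#' @export
read_annotations <- function(path, sequence_lengths) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"))
  out <- list()
  for (id in unique(bed$chrom)) {
    rows <- bed[bed$chrom == id, , drop = FALSE]
    if (!id %in% names(sequence_lengths)) {
      stop(sprintf("annotation record '%s' has no matching sequence", id),
           call. = FALSE)
    }
    len <- sequence_lengths[[id]]
    bad <- rows$start < 0 | rows$end > len | rows$start >= rows$end
    if (any(bad)) {
      b <- rows[which(bad)[1], ]
      stop(sprintf(
        "annotation record '%s' interval [%d, %d) out of bounds for length %d",
        id, b$start, b$end, len), call. = FALSE)
    }
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    merged <- matrix(c(rows$start[1], rows$end[1]), ncol = 2)
    merged_any <- FALSE
    for (i in seq_len(nrow(rows))[-1]) {
      last <- nrow(merged)
      if (rows$start[i] <= merged[last, 2]) {
        merged[last, 2] <- max(merged[last, 2], rows$end[i])
        merged_any <- TRUE
      } else {
        merged <- rbind(merged, c(rows$start[i], rows$end[i]))
      }
    }
    if (merged_any) {
      warning(sprintf("overlapping exon intervals merged for '%s'", id),
              call. = FALSE)
    }
    colnames(merged) <- c("start", "end")
    storage.mode(merged) <- "integer"
    out[[id]] <- merged
  }
  out
}

#' Voss binary indicator mapping
#'
#' Converts a DNA string into four binary indicator tracks u_A, u_C, u_G,
#' u_T marking the presence (1) or absence (0) of each nucleotide. Columns
#' are one-hot at unambiguous bases; IUPAC ambiguity codes (N, R, Y, ...)
#' map to all-zero columns and are counted in `n_ambiguous`, keeping the
#' tracks strictly binary.
#'
#' @param sequence non-empty DNA string (IUPAC alphabet; U treated as T).
#' @param id optional sequence id carried along.
#' @return an object of class `indicator_matrix`: list with `id`, `tracks`
#'   (4 x N binary integer matrix with rownames A, C, G, T) and
#'   `n_ambiguous`.
#' @export
voss_map <- function(sequence, id = "seq") {
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("'sequence' must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  chars[chars == "U"] <- "T"
  bad <- !(chars %in% IUPAC_CODES)
  if (any(bad)) {
    stop(sprintf("character '%s' at position %d is not a IUPAC code",
                 chars[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  n <- length(chars)
  tracks <- matrix(0L, nrow = 4, ncol = n, dimnames = list(BASES, NULL))
  for (b in BASES) tracks[b, chars == b] <- 1L
  structure(
    list(id = id, tracks = tracks,
         n_ambiguous = sum(colSums(tracks) == 0L)),
    class = "indicator_matrix")
}
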