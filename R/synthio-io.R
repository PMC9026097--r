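format_error <- function(path, line, msg) {
  stop(sprintf("format error in %s, line %d: %s", path, line, msg), call. = FALSE)
}

writer_header <- function(seed = NA) {
  sprintf("# modscape %s seed=%s",
          as.character(utils::packageVersion("modscape")), as.character(seed))
}

read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#")
  list(lines = lines[keep], numbers = which(keep))
}

#' Read / write a gene x sample expression matrix (tab-delimited)
#'
#' First column holds gene IDs, the header row holds sample IDs. Lines starting
#' with `#` are comments. `write_expression_tsv()` followed by
#' `read_expression_tsv()` is the identity up to 15-significant-digit float
#' formatting.
#'
#' @param path file path.
#' @param groups optional named character vector mapping sample -> group; when
#'   supplied the result is an [expression_matrix()].
#' @return a numeric matrix (an [expression_matrix()] when `groups` is given).
#' @export
read_expression_tsv <- function(path, groups = NULL) {
  tx <- read_text_lines(path)
  if (length(tx$lines) < 2) stop("expression file needs a header and data", call. = FALSE)
  fields <- strsplit(tx$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  samples <- header[-1L]
  body <- fields[-1L]
  nums <- tx$numbers[-1L]
  lens <- lengths(body)
  if (any(lens != n_col)) {
    i <- which(lens != n_col)[1L]
    format_error(path, nums[i],
                 sprintf("expected %d fields, found %d", n_col, lens[i]))
  }
  flat <- unlist(body, use.names = FALSE)
  cells <- matrix(flat, nrow = length(body), byrow = TRUE)
  genes <- cells[, 1L]
  vals <- suppressWarnings(matrix(as.numeric(cells[, -1L, drop = FALSE]),
                                  nrow = length(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    format_error(path, nums[bad[1L]],
                 sprintf("non-numeric cell '%s'", cells[bad[1L], bad[2L] + 1L]))
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    first_dup_line <- nums[which(duplicated(genes))[1L]]
    format_error(path, first_dup_line,
                 sprintf("duplicate gene ID '%s'", dup[1L]))
  }
  dimnames(vals) <- list(genes, samples)
  if (!is.null(groups)) expression_matrix(vals, groups) else vals
}

#' @rdname read_expression_tsv
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param seed seed recorded in the header comment (for generated data).
#' @export
write_expression_tsv <- function(x, path, seed = NA) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header(seed), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) paste(format(v, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Directional gene signatures
#'
#' A signature is a named, optionally directional gene set (e.g. the up- and
#' down-regulated halves of a transcription-factor activation signature).
#'
#' @param name signature name.
#' @param members unique, nonempty character vector of gene IDs.
#' @param direction one of `"up"`, `"down"`, `"activated"`, `"suppressed"`,
#'   `"none"`.
#' @param note free-text source note (kept in the GMT description field).
#' @return an object of class `signature_set`.
#' @export
signature_set <- function(name, members, direction = "none", note = "") {
  direction <- match.arg(direction, c("up", "down", "activated", "suppressed", "none"))
  members <- as.character(members)
  if (length(members) == 0) stop("signature members must be nonempty", call. = FALSE)
  if (anyDuplicated(members)) stop("signature members must be unique", call. = FALSE)
  structure(list(name = name, direction = direction, members = members, note = note),
            class = "signature_set")
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated. The
#' description field is retained as the signature `note`; if it matches one of
#' the direction keywords (`up`, `down`, `activated`, `suppressed`) the
#' signature direction is set accordingly.
#'
#' @param path file path.
#' @return a named list of [signature_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  tx <- read_text_lines(path)
  sets <- list()
  for (i in seq_along(tx$lines)) {
    f <- strsplit(tx$lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3) {
      format_error(path, tx$numbers[i], "GMT line needs name, description and >= 1 gene")
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      format_error(path, tx$numbers[i],
                   sprintf("duplicate gene '%s' in set '%s'",
                           genes[duplicated(genes)][1L], f[1L]))
    }
    dir <- if (tolower(f[2L]) %in% c("up", "down", "activated", "suppressed")) {
      tolower(f[2L])
    } else {
      "none"
    }
    sets[[f[1L]]] <- signature_set(f[1L], genes, direction = dir, note = f[2L])
  }
  sets
}

#' @rdname read_gmt
#' @param sets a list of [signature_set()] objects.
#' @param seed seed recorded in the header comment.
#' @export
write_gmt <- function(sets, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header(seed), con)
  for (s in sets) {
    note <- if (nzchar(s$note)) s$note else s$direction
    writeLines(paste(c(s$name, note, s$members), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write BED intervals (0-based, half-open)
#'
#' Accepts 3-column (chrom, start, end) or 6-column (plus name, score, strand)
#' BED. The strand column is optional and defaults to `+`.
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  tx <- read_text_lines(path)
  out <- vector("list", length(tx$lines))
  for (i in seq_along(tx$lines)) {
    f <- strsplit(tx$lines[i], "\t", fixed = TRUE)[[1L]]
    if (!length(f) %in% c(3L, 4L, 5L, 6L)) {
      format_error(path, tx$numbers[i], "BED line needs 3-6 tab-separated fields")
    }
    start <- suppressWarnings(as.numeric(f[2L]))
    end <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(start) || is.na(end)) {
      format_error(path, tx$numbers[i], "non-numeric start/end")
    }
    if (start >= end) {
      format_error(path, tx$numbers[i], "start must be < end (0-based half-open)")
    }
    out[[i]] <- data.frame(
      chrom = f[1L], start = start, end = end,
      name = if (length(f) >= 4) f[4L] else sprintf("interval_%d", i),
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5L])) else 0,
      strand = if (length(f) >= 6) f[6L] else "+",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' @rdname read_bed
#' @param bed data.frame with at least chrom, start, end.
#' @param seed seed recorded in the header comment.
#' @export
write_bed <- function(bed, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_header(seed), con)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(bed))
  lines <- do.call(paste, c(lapply(cols, function(cl) {
    v <- bed[[cl]]
    if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE) else as.character(v)
  }), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] adding the contract that headers are unique
#' gene IDs (the first whitespace-delimited token is used).
#'
#' @param path file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop(sprintf("format error in %s: duplicate FASTA header '%s'",
                 path, names(seqs)[duplicated(names(seqs))][1L]), call. = FALSE)
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
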