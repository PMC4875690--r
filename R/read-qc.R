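#' @title FASTQ quality filtering and trimming
#' @description Implements the pre-alignment read-cleaning rules of the
#' pipeline as a standalone stage: N-content and low-quality discard rules,
#' adapter screening, low-quality-run trimming, and a post-trim length cut,
#' plus exact duplicate-pair removal.
#' @name read_qc
NULL

phred_from_string <- function(qual, offset = 33L) {
  utf8ToInt(qual) - offset
}

# Ungapped adapter scan: slides the adapter across every offset of the read
# and reports a hit when some window of >= 11 aligned bases (i.e. more than
# 10 bp) matches with at most `max_mismatch` mismatches.
adapter_hit <- function(seq_chars, adapter, min_match = 11L,
                        max_mismatch = 2L) {
  a_chars <- strsplit(adapter, "")[[1]]
  ls <- length(seq_chars)
  la <- length(a_chars)
  if (min(ls, la) < min_match) return(FALSE)
  for (off in seq(-(la - min_match), ls - min_match)) {
    # adapter position j aligns read position off + j
    j0 <- max(1L, 1L - off)
    j1 <- min(la, ls - off)
    if (j1 - j0 + 1L < min_match) next
    mism <- a_chars[j0:j1] != seq_chars[(off + j0):(off + j1)]
    n <- length(mism)
    cs <- c(0L, cumsum(mism))
    w <- min_match
    if (any(cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)] <= max_mismatch)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Apply the quality rules to one read
#'
#' Rules in order: (1) discard when >= 10% of bases are N; (2) discard when
#' more than 65% of bases have Phred <= 7; (3) discard on an adapter match
#' of more than 10 bp allowing up to 2 mismatches; (4) trim at the first
#' run of 3 consecutive bases with Phred <= 13, keeping the 5' prefix
#' before the run; (5) discard when the post-trim read is shorter than
#' 45 bp.
#'
#' @param sequence read sequence (string over A/C/G/T/N).
#' @param quality Phred quality string (offset 33) of the same length.
#' @param adapters character vector of adapter sequences (may be empty).
#' @return list with `action` (`"keep"` / `"discard"`), `reason` (one of
#'   `"n_fraction"`, `"low_quality"`, `"adapter"`, `"short"`, or `NA` when
#'   kept), `sequence`, `quality` (trimmed when kept), and
#'   `bases_trimmed`.
#' @export
qc_read <- function(sequence, quality, adapters = character()) {
  if (nchar(sequence) != nchar(quality)) {
    stop("format error: sequence and quality lengths differ")
  }
  chars <- strsplit(sequence, "")[[1]]
  phred <- phred_from_string(quality)
  if (any(phred < 0)) stop("Phred values must be >= 0")
  len <- length(chars)
  discard <- function(reason) list(action = "discard", reason = reason,
                                   sequence = NA_character_,
                                   quality = NA_character_,
                                   bases_trimmed = 0L)
  if (sum(chars == "N") / len >= 0.10) return(discard("n_fraction"))
  if (sum(phred <= 7) / len > 0.65) return(discard("low_quality"))
  for (a in adapters) {
    if (adapter_hit(chars, a)) return(discard("adapter"))
  }
  low <- phred <= 13
  run3 <- if (len >= 3L) {
    which(low & c(low[-1], FALSE) & c(low[-(1:2)], FALSE, FALSE))
  } else {
    integer(0)
  }
  trimmed <- 0L
  if (length(run3) > 0) {
    keep_len <- run3[1] - 1L
    trimmed <- len - keep_len
    sequence <- substr(sequence, 1L, keep_len)
    quality <- substr(quality, 1L, keep_len)
    len <- keep_len
  }
  if (len < 45L) return(discard("short"))
  list(action = "keep", reason = NA_character_, sequence = sequence,
       quality = quality, bases_trimmed = trimmed)
}

#' Apply the quality rules to a read set
#'
#' @param reads data.frame with `id`, `sequence`, `quality` (and optionally
#'   `mate`), e.g. from [read_fastq()].
#' @param adapters character vector of adapter sequences.
#' @return list with `reads` (kept reads, trimmed) and `report`: counts of
#'   input, kept, per-rule discards (`n_fraction`, `low_quality`,
#'   `adapter`, `short`), reads trimmed, and total bases trimmed.
#'   `kept + discarded == input` always.
#' @export
qc_reads <- function(reads, adapters = character()) {
  n <- nrow(reads)
  res <- lapply(seq_len(n), function(i)
    qc_read(reads$sequence[i], reads$quality[i], adapters))
  action <- vapply(res, `[[`, character(1), "action")
  reason <- vapply(res, `[[`, character(1), "reason")
  kept <- which(action == "keep")
  out <- reads[kept, , drop = FALSE]
  out$sequence <- vapply(res[kept], `[[`, character(1), "sequence")
  out$quality <- vapply(res[kept], `[[`, character(1), "quality")
  trimmed_b <- vapply(res, `[[`, integer(1), "bases_trimmed")
  report <- list(
    n_input = n,
    n_kept = length(kept),
    n_discarded = n - length(kept),
    discard_n_fraction = sum(reason == "n_fraction", na.rm = TRUE),
    discard_low_quality = sum(reason == "low_quality", na.rm = TRUE),
    discard_adapter = sum(reason == "adapter", na.rm = TRUE),
    discard_short = sum(reason == "short", na.rm = TRUE),
    n_trimmed = sum(trimmed_b[kept] > 0),
    bases_trimmed = sum(trimmed_b[kept])
  )
  rownames(out) <- NULL
  list(reads = out, report = report)
}

#' Remove exact duplicate read pairs
#'
#' Retains the first occurrence of each exact (mate-1 sequence, mate-2
#' sequence) combination; later identical pairs are dropped. Mates are
#' matched by id and must pair one-to-one.
#'
#' @param reads1,reads2 data.frames with `id`, `sequence` (mate 1 / mate 2,
#'   same read order or matchable by id).
#' @return list with `reads1`, `reads2` (deduplicated, same order), and
#'   `report` (`n_input_pairs`, `n_kept_pairs`, `n_duplicate_pairs`).
#' @export
deduplicate_pairs <- function(reads1, reads2) {
  if (nrow(reads1) != nrow(reads2)) {
    stop("pairing error: different numbers of mate-1 and mate-2 reads")
  }
  m <- match(reads1$id, reads2$id)
  if (anyNA(m) || anyDuplicated(reads1$id) || anyDuplicated(reads2$id)) {
    stop("pairing error: orphan or duplicated mate ids")
  }
  reads2 <- reads2[m, , drop = FALSE]
  key <- paste(reads1$sequence, reads2$sequence, sep = "\r")
  keep <- !duplicated(key)
  list(
    reads1 = reads1[keep, , drop = FALSE],
    reads2 = reads2[keep, , drop = FALSE],
    report = list(n_input_pairs = nrow(reads1),
                  n_kept_pairs = sum(keep),
                  n_duplicate_pairs = sum(!keep))
  )
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # readQualityScaledDNAStringSet warns about dropping the mcols it created
  # itself while attaching qualities; nothing of value is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(
    id = names(x),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}
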