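# Exact-match k-mer specificity screen for dsRNA trigger fragments.
#
# The siRNAs processed from a dsRNA hairpin are ~21 nt, so a transcript that
# shares no exact 21-nt stretch with the trigger fragment cannot be silenced
# through perfect-match siRNA pairing. The screen reports every maximal shared
# exact substring of length >= k between a fragment and each candidate
# off-target transcript, on both strands (dsRNA is double-stranded, so both
# orientations are biologically active).

#' Read / write FASTA as a sequence tibble
#'
#' Sequences are validated against the alphabet `{A, C, G, T, N}`
#' (case-insensitive; U is accepted and stored as T) and held upper-case.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(ss), seq = vapply(as.character(ss), clean_seq,
                                              character(1), USE.NAMES = FALSE))
}

#' @rdname read_fasta
#' @param x Tibble with columns `id`, `seq`.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(vapply(x$seq, clean_seq, character(1),
                                        USE.NAMES = FALSE))
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

clean_seq <- function(seq) {
  s <- toupper(gsub("U", "T", seq, fixed = FALSE))
  if (nchar(s) == 0) stop("Empty sequence.", call. = FALSE)
  if (grepl("[^ACGTN]", s)) {
    stop("Invalid character in sequence (alphabet is A/C/G/T/N/U).", call. = FALSE)
  }
  s
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All maximal shared exact substrings of length >= k between two plain
# character sequences, forward orientation only. k-mers containing N never
# match. Returns a data frame of 0-based half-open coordinates.
maximal_matches_fwd <- function(q, s, k) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < k || ns < k) {
    return(tibble::tibble(query_start = integer(), subject_start = integer(),
                          length = integer()))
  }
  qk <- substring(q, 1:(nq - k + 1), k:nq)
  sk <- substring(s, 1:(ns - k + 1), k:ns)
  keep_q <- !grepl("N", qk, fixed = TRUE)
  keep_s <- !grepl("N", sk, fixed = TRUE)
  s_index <- split(which(keep_s), sk[keep_s])
  qi_all <- which(keep_q & qk %in% names(s_index))
  if (length(qi_all) == 0) {
    return(tibble::tibble(query_start = integer(), subject_start = integer(),
                          length = integer()))
  }
  hits_j <- s_index[qk[qi_all]]
  qi <- rep.int(qi_all, lengths(hits_j))
  sj <- unlist(hits_j, use.names = FALSE)
  # Matching k-windows on the same diagonal that advance in lockstep belong
  # to one longer exact match; merge each run of consecutive windows into a
  # single maximal match.
  d <- sj - qi
  o <- order(d, qi)
  qi <- qi[o]; d <- d[o]
  new_run <- c(TRUE, diff(d) != 0 | diff(qi) != 1)
  run_id <- cumsum(new_run)
  first <- which(new_run)
  run_len <- tabulate(run_id)
  tibble::tibble(
    query_start = qi[first] - 1L,
    subject_start = qi[first] + d[first] - 1L,
    length = run_len + k - 1L
  )
}

#' Shared k-mer scan between a dsRNA fragment and one transcript
#'
#' Finds every maximal exact shared substring of length >= `k` between the
#' query and the subject, scanning the subject in both orientations. A
#' maximal match cannot be extended on either side and remain exact; the
#' number of matching k-windows it contains is `length - k + 1`.
#'
#' Coordinates are 0-based, half-open, on the forward orientation of each
#' stored sequence; for `-` strand matches `subject_start` is the position on
#' the subject's reverse complement (position 0 = the last base of the stored
#' subject).
#'
#' @param query,subject Sequences: a single-row tibble from [read_fasta()], a
#'   list with `id`/`seq`, or a bare character string.
#' @param k Minimum exact-match length in nt (default 21, the canonical siRNA
#'   length; minimum 8).
#' @return A `kmer_match_report`: tibble of matches (`query_id`, `subject_id`,
#'   `query_start`, `subject_start`, `length`, `strand`, `n_windows`) with
#'   attribute `k`.
#' @examples
#' shared_kmer_scan("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA", k = 21)
#' @export
shared_kmer_scan <- function(query, subject, k = 21) {
  if (!is.numeric(k) || length(k) != 1 || k < 8) {
    stop("`k` must be a single number >= 8.", call. = FALSE)
  }
  k <- as.integer(k)
  q <- as_seq_record(query, "query")
  s <- as_seq_record(subject, "subject")
  fwd <- maximal_matches_fwd(q$seq, s$seq, k)
  rev <- maximal_matches_fwd(q$seq, revcomp(s$seq), k)
  out <- dplyr::bind_rows(
    dplyr::mutate(fwd, strand = "+"),
    dplyr::mutate(rev, strand = "-")
  )
  out <- tibble::tibble(
    query_id = rep(q$id, nrow(out)), subject_id = rep(s$id, nrow(out)),
    query_start = out$query_start, subject_start = out$subject_start,
    length = out$length, strand = out$strand,
    n_windows = out$length - k + 1L
  )
  structure(out, class = c("kmer_match_report", class(out)), k = k)
}

as_seq_record <- function(x, default_id) {
  if (is.character(x) && length(x) == 1) {
    list(id = default_id, seq = clean_seq(x))
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("Expected a single sequence.", call. = FALSE)
    list(id = x$id[[1]], seq = clean_seq(x$seq[[1]]))
  } else if (is.list(x) && !is.null(x$seq)) {
    list(id = x$id %||% default_id, seq = clean_seq(x$seq))
  } else {
    stop("Cannot interpret sequence input.", call. = FALSE)
  }
}

#' Screen a dsRNA fragment against a transcript panel
#'
#' Runs [shared_kmer_scan()] of the fragment against every transcript and
#' summarizes per-transcript match counts. The overall verdict is `"clean"`
#' only if no transcript shares any exact match of length >= `k` with the
#' fragment.
#'
#' @param fragment The dsRNA trigger fragment (see [shared_kmer_scan()] for
#'   accepted forms).
#' @param transcripts Tibble of candidate off-target transcripts (columns
#'   `id`, `seq`), e.g. from [read_fasta()].
#' @param k Minimum exact-match length (default 21 nt).
#' @return A `screen_result`: list with `summary` (tibble: `subject_id`,
#'   `n_matches`, `n_windows`, `flagged`), `matches` (row-bound match
#'   reports), `verdict` (`"clean"` or `"matches_found"`) and `k`.
#' @export
screen_fragment <- function(fragment, transcripts, k = 21) {
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0) {
    stop("`transcripts` must be a non-empty tibble with columns id, seq.",
         call. = FALSE)
  }
  reports <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    shared_kmer_scan(fragment, transcripts[i, ], k = k)
  })
  matches <- dplyr::bind_rows(reports)
  summary <- tibble::tibble(
    subject_id = transcripts$id,
    n_matches = vapply(reports, nrow, integer(1)),
    n_windows = vapply(reports, function(r) sum(r$n_windows), integer(1))
  )
  summary$flagged <- summary$n_matches > 0
  structure(
    list(summary = summary, matches = matches,
         verdict = if (any(summary$flagged)) "matches_found" else "clean",
         k = k),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> k = %d: %s (%d of %d transcripts flagged)\n",
              x$k, x$verdict, sum(x$summary$flagged), nrow(x$summary)))
  if (any(x$summary$flagged)) {
    print(as.data.frame(dplyr::filter(x$summary, .data$flagged)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a k-mer match report or screen summary as TSV
#'
#' @param x A `kmer_match_report` or `screen_result`.
#' @param path Output path.
#' @export
write_match_report <- function(x, path) {
  tbl <- if (inherits(x, "screen_result")) x$matches else x
  readr::write_tsv(tibble::as_tibble(tbl), path)
  invisible(path)
}
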