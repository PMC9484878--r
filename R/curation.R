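#' Sequence-level dataset curation filters
#'
#' Applies the standard curation rules used to assemble the localization
#' dataset: drop proteins shorter than `min_len` residues, longer than
#' `max_len` residues, or containing residues outside the standard
#' 20-letter amino-acid alphabet (ambiguity codes such as `X`).  Boundary
#' lengths (`min_len`, `max_len` exactly) are kept.  A record failing
#' several rules is attributed to the first failing rule, in the order
#' too_short, too_long, ambiguous_residue, so removal counts are
#' deterministic and sum with the kept set to the input size.
#'
#' Selenocysteine (`U`) and pyrrolysine (`O`) are not in the default
#' alphabet and therefore count as ambiguous; pass a wider `alphabet` to
#' keep them.  Redundancy reduction (CD-HIT-style clustering) is assumed
#' to have happened upstream.
#'
#' @param records Data frame with columns `id`, `sequence` (and optionally
#'   `class_index`); one row per protein.
#' @param min_len,max_len Inclusive length bounds for kept sequences.
#' @param alphabet Character vector of allowed residues.
#' @return A list with `kept` (tibble, input order preserved), `removed`
#'   (tibble `id`, `reason`) and `report` (tibble `reason`, `n` covering
#'   all three rules).
#' @examples
#' recs <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   sequence = c(strrep("ACDEFGHIKLMNPQRSTVWY", 5), "ACDX", strrep("A", 10)))
#' filter_sequences(recs)$report
#' @export
filter_sequences <- function(records, min_len = 50L, max_len = 5000L,
                             alphabet = c("A","C","D","E","F","G","H","I",
                                          "K","L","M","N","P","Q","R","S",
                                          "T","V","W","Y")) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a nonempty data frame")
  }
  stopifnot(all(c("id", "sequence") %in% names(records)),
            all(nzchar(records$id)))
  if (min_len >= max_len) abort("`min_len` must be below `max_len`")
  records <- as_tibble(records)
  len <- nchar(records$sequence)
  clean <- vapply(strsplit(toupper(records$sequence), ""), function(ch) {
    all(ch %in% alphabet)
  }, logical(1))
  reason <- rep(NA_character_, nrow(records))
  reason[!clean] <- "ambiguous_residue"
  reason[len > max_len] <- "too_long"       # earlier rules overwrite later ones
  reason[len < min_len] <- "too_short"
  kept <- records[is.na(reason), , drop = FALSE]
  removed <- tibble(id = records$id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  rules <- c("too_short", "too_long", "ambiguous_residue")
  report <- tibble(reason = rules,
                   n = vapply(rules, function(r) sum(removed$reason == r),
                              integer(1)))
  list(kept = kept, removed = removed, report = report)
}

#' Read protein records from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning the tibble
#' shape [filter_sequences()] consumes.  The FASTA description line up to
#' the first whitespace becomes the id.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta_records <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta_records() needs the Biostrings package")
  }
  seqs <- Biostrings::readAAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(seqs)),
         sequence = as.character(seqs))
}
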