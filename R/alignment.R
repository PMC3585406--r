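#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Clustal files into a two-column tibble (`id`,
#' `seq`).  All sequences must have equal aligned length and unique ids.
#'
#' @param path Path to an aligned FASTA or Clustal file.
#' @param format `"fasta"`, `"clustal"`, or `"auto"` (sniff the first line).
#' @return An alignment tibble with attribute `n_columns`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such alignment file: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    aln <- new_alignment(names(ss), unname(as.character(ss)))
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- as.character(ma)
    aln <- new_alignment(names(seqs), unname(seqs))
  }
  aln
}

#' Construct an alignment tibble
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of equal-length aligned sequences
#'   (20 amino acid letters plus `-`).
#' @return A tibble with columns `id` and `seq`.
#' @export
new_alignment <- function(ids, seqs) {
  if (length(ids) != length(seqs)) abort("ids and seqs differ in length")
  if (!length(ids)) abort("empty alignment")
  if (anyDuplicated(ids)) abort("alignment ids are not unique")
  len <- unique(nchar(seqs))
  if (length(len) != 1) abort("aligned sequences differ in length")
  if (len < 1) abort("alignment has zero columns")
  out <- tibble(id = as.character(ids), seq = toupper(seqs))
  attr(out, "n_columns") <- len
  class(out) <- c("aa_alignment", class(tibble()))
  out
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

#' Map alignment columns to reference residue numbers
#'
#' Columns where the reference sequence has a gap map to nothing; mapped
#' columns are numbered consecutively starting at `start`.
#'
#' @param aln An alignment tibble.
#' @param reference_id Id of the reference sequence.
#' @param start Residue number of the reference's first non-gap position.
#' @return Tibble with columns `column` (1-based alignment column) and `site`.
#' @export
align_to_reference <- function(aln, reference_id, start = 1) {
  if (!nrow(aln)) abort("empty alignment")
  ref <- aln$seq[aln$id == reference_id]
  if (!length(ref)) abort(paste0("reference id '", reference_id, "' not in alignment"))
  chars <- strsplit(ref, "")[[1]]
  keep <- which(chars != "-")
  tibble(column = keep, site = start + seq_along(keep) - 1L)
}

#' Per-column residue profiles at selected sites
#'
#' Counts residues (gap included as its own category) in the alignment
#' columns corresponding to reference sites.
#'
#' @inheritParams align_to_reference
#' @param sites Integer vector of reference sites; `NULL` profiles every
#'   mapped column.
#' @return Tibble with columns `site`, `residue`, `count`, `n_total`, `freq`.
#' @export
column_profiles <- function(aln, reference_id, sites = NULL, start = 1) {
  map <- align_to_reference(aln, reference_id, start)
  if (is.null(sites)) sites <- map$site
  bad <- setdiff(sites, map$site)
  if (length(bad)) abort(paste0("site(s) outside reference range: ", paste(bad, collapse = ", ")))
  m <- aln_matrix(aln)
  n <- nrow(m)
  purrr::map(sites, function(s) {
    col <- m[, map$column[map$site == s]]
    tab <- table(col)
    tibble(site = s, residue = names(tab), count = as.integer(tab),
           n_total = n, freq = as.integer(tab) / n)
  }) |> list_rbind() |> arrange(.data$site, desc(.data$count))
}

profiles_from_counts <- function(df) {
  # normalize a (site, residue, count) table into the column_profiles layout
  df |>
    group_by(.data$site) |>
    mutate(n_total = sum(.data$count), freq = .data$count / .data$n_total) |>
    ungroup() |>
    arrange(.data$site, desc(.data$count))
}

#' Donor/acceptor substitution candidates from a pairwise alignment
#'
#' One candidate per aligned, non-gap, differing column, expressed in the
#' acceptor's residue numbering.  Identical columns and columns where either
#' sequence gaps are excluded.
#'
#' @param pair_aln Alignment tibble holding exactly the acceptor and donor.
#' @param acceptor_id,donor_id Sequence ids.
#' @param start Residue number of the acceptor's first non-gap position.
#' @return Tibble with columns `site`, `wt_residue`, `target_residue`.
#' @export
pairwise_candidates <- function(pair_aln, acceptor_id, donor_id, start = 1) {
  for (id in c(acceptor_id, donor_id)) {
    if (!id %in% pair_aln$id) abort(paste0("sequence '", id, "' not in alignment"))
  }
  acc <- strsplit(pair_aln$seq[pair_aln$id == acceptor_id], "")[[1]]
  don <- strsplit(pair_aln$seq[pair_aln$id == donor_id], "")[[1]]
  map <- align_to_reference(pair_aln, acceptor_id, start)
  keep <- map$column[acc[map$column] != "-" & don[map$column] != "-" &
                       acc[map$column] != don[map$column]]
  tibble(
    site = map$site[match(keep, map$column)],
    wt_residue = acc[keep],
    target_residue = don[keep]
  )
}
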