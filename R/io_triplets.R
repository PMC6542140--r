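#' Triplet alignment dataset
#'
#' A `triplet_dataset` is a list of independent three-sequence alignments:
#' two ingroup sequences (S. invicta and/or S. richteri) plus an outgroup
#' (S. fugax), each of fixed length (96 bp by default for RAD loci). Each
#' triplet carries a pair configuration: `II` (two invicta), `RR` (two
#' richteri) or `RI` (one of each).
#'
#' @param triplets Tibble with columns `locus_id`, `pair_config`,
#'   `seq_a`, `seq_b`, `seq_out` (character sequences over ACGTN).
#' @param spacing_ok Logical flag recording that the source loci satisfied
#'   the minimum physical spacing (>= 2000 bp in the study design).
#' @return An object of class `triplet_dataset`.
#' @export
triplet_dataset <- function(triplets, spacing_ok = TRUE) {
  t <- tibble::as_tibble(triplets)
  stopifnot(all(c("locus_id", "pair_config", "seq_a", "seq_b", "seq_out") %in% names(t)))
  if (anyDuplicated(t$locus_id)) stop("duplicate triplet locus ids", call. = FALSE)
  if (!all(t$pair_config %in% c("II", "RR", "RI")))
    stop("pair_config must be one of II, RR, RI", call. = FALSE)
  for (i in seq_len(nrow(t))) {
    lens <- nchar(c(t$seq_a[i], t$seq_b[i], t$seq_out[i]))
    if (length(unique(lens)) != 1)
      stop(sprintf("unequal sequence lengths in locus '%s' (%s)",
                   t$locus_id[i], paste(lens, collapse = "/")), call. = FALSE)
    if (grepl("[^ACGTN]", paste0(t$seq_a[i], t$seq_b[i], t$seq_out[i])))
      stop(sprintf("non-ACGTN character in locus '%s'", t$locus_id[i]), call. = FALSE)
  }
  structure(list(triplets = t, spacing_ok = isTRUE(spacing_ok)),
            class = "triplet_dataset")
}

#' @export
print.triplet_dataset <- function(x, ...) {
  cfg <- table(x$triplets$pair_config)
  cat(sprintf("<triplet_dataset> %d loci (%s), length %s bp\n",
              nrow(x$triplets),
              paste(names(cfg), cfg, sep = "=", collapse = ", "),
              if (nrow(x$triplets)) nchar(x$triplets$seq_a[1]) else "?"))
  invisible(x)
}

#' @export
length.triplet_dataset <- function(x) nrow(x$triplets)

#' Read triplet alignments from multi-FASTA
#'
#' Expects three records per locus with ids of the form `locus|role`, where
#' role is one of `a`, `b`, `out`, plus `locus|config=XX` on the `a` record
#' (XX in II/RR/RI). Sequences must be equal length within a locus; `N` is
#' allowed and treated as missing at that site downstream.
#'
#' @param path Multi-FASTA file.
#' @return A [triplet_dataset()].
#' @export
read_triplets <- function(path) {
  if (!file.exists(path)) stop("triplet FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  locus <- vapply(parts, `[`, character(1), 1)
  role <- vapply(parts, `[`, character(1), 2)
  cfg_raw <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                    character(1))
  if (any(is.na(role)))
    stop("record id without '|role' suffix: ", ids[which(is.na(role))[1]], call. = FALSE)
  sq <- unname(as.character(seqs))
  rows <- lapply(unique(locus), function(l) {
    idx <- which(locus == l)
    r <- role[idx]
    if (!setequal(r, c("a", "b", "out")))
      stop(sprintf("locus '%s' needs exactly roles a, b, out", l), call. = FALSE)
    cfg <- sub("^config=", "", stats::na.omit(cfg_raw[idx])[1])
    tibble::tibble(
      locus_id = l, pair_config = cfg,
      seq_a = sq[idx[r == "a"]], seq_b = sq[idx[r == "b"]],
      seq_out = sq[idx[r == "out"]]
    )
  })
  triplet_dataset(dplyr::bind_rows(rows))
}

#' Write triplet alignments to multi-FASTA
#'
#' Inverse of [read_triplets()]: `read_triplets(write_triplets(x))` is the
#' identity.
#'
#' @param x A [triplet_dataset()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_triplets <- function(x, path) {
  stopifnot(inherits(x, "triplet_dataset"))
  t <- x$triplets
  ids <- c(
    paste0(t$locus_id, "|a|config=", t$pair_config),
    paste0(t$locus_id, "|b"),
    paste0(t$locus_id, "|out")
  )
  sq <- c(t$seq_a, t$seq_b, t$seq_out)
  ord <- as.vector(t(matrix(seq_along(ids), ncol = 3)))
  dss <- Biostrings::DNAStringSet(sq[ord])
  names(dss) <- ids[ord]
  Biostrings::writeXStringSet(dss, path, width = 20000L)
  invisible(path)
}

#' Read a structured-text run configuration
#'
#' YAML file with filter, prior, simulation and output settings; unknown keys
#' are preserved. The seed must be a non-negative integer.
#'
#' @param path YAML file.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$seed)) {
    if (cfg$seed < 0 || cfg$seed != round(cfg$seed))
      stop("seed must be a non-negative integer", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}
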