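#' Mimotope peptide sets
#'
#' A mimotope set is the collection of 12-mer phage-display peptides
#' sequenced for one mAb, with the clone count of each unique peptide. The
#' peptide frequency of a unique peptide is its clone count divided by the
#' total number of clones sequenced for that mAb.
#'
#' @param mab_id Identifier of the mAb.
#' @param peptides Named integer vector (names = peptide sequences, values =
#'   clone counts) or a data frame with columns \code{peptide}, \code{count}.
#' @return Object of class \code{"pep_mimotope_set"}.
#' @export
mimotope_set <- function(mab_id, peptides) {
  if (is.data.frame(peptides)) {
    counts <- tapply(peptides$count, toupper(peptides$peptide), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- tapply(as.integer(peptides), toupper(names(peptides)), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (!length(counts) || sum(counts) < 1) stop("empty mimotope set: ", mab_id)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", names(counts))
  if (any(bad))
    stop("non-amino-acid characters in peptide(s) of ", mab_id, ": ",
         paste(names(counts)[bad], collapse = ", "))
  total <- sum(counts)
  if (total < 12)
    warning("mAb ", mab_id, ": only ", total,
            " clones (at least 12 are expected)")
  structure(list(mab_id = mab_id, counts = counts, total_clones = total),
            class = "pep_mimotope_set")
}

#' @export
print.pep_mimotope_set <- function(x, ...) {
  cat("Mimotope set for", x$mab_id, "-", length(x$counts),
      "unique peptide(s),", x$total_clones, "clones\n")
  invisible(x)
}

#' Per-peptide clone frequencies of a mimotope set
#'
#' @param set A [mimotope_set()].
#' @return Named numeric vector summing to 1.
#' @export
peptide_frequencies <- function(set) {
  stopifnot(inherits(set, "pep_mimotope_set"))
  set$counts / set$total_clones
}

#' Pairwise mimotope redundancy score
#'
#' For mAbs X and Y the redundancy is the sum over their common peptides of
#' the product of the peptide's within-mAb frequencies, expressed in
#' percent:
#' \deqn{Red_{XY} = \sum_i X_{n_i} Y_{m_i} \times 100}
#' where \eqn{X_{n_i}} (\eqn{Y_{m_i}}) is the frequency of the i-th common
#' peptide in X (Y). Peptide identity is exact string equality. The score is
#' symmetric, bounded in [0, 100], zero for disjoint sets and 100 only when
#' both sets consist of one identical peptide. The self-score
#' \eqn{Red_{XX}} is the Simpson concentration of the set times 100.
#'
#' @param x,y [mimotope_set()] objects.
#' @return Redundancy in percent.
#' @examples
#' a <- mimotope_set("A", c(PEPTIDEPEPTI = 6, AAAAAAAAAAAA = 6))
#' b <- mimotope_set("B", c(PEPTIDEPEPTI = 3, CCCCCCCCCCCC = 9))
#' redundancy(a, b)  # (6/12) * (3/12) * 100 = 12.5
#' @export
redundancy <- function(x, y) {
  fx <- peptide_frequencies(x)
  fy <- peptide_frequencies(y)
  common <- intersect(names(fx), names(fy))
  if (!length(common)) return(0)
  sum(fx[common] * fy[common]) * 100
}

#' Redundancy matrix over a mAb library
#'
#' @param sets List of [mimotope_set()] objects (>= 2).
#' @return Symmetric matrix of class \code{"pep_redundancy"} with
#'   \code{Red(X, Y)} in percent; the diagonal holds the self-redundancy
#'   (Simpson concentration x 100).
#' @export
redundancy_matrix <- function(sets) {
  stopifnot(length(sets) >= 2)
  ids <- vapply(sets, function(s) s$mab_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated mAb ids in `sets`")
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  freqs <- lapply(sets, peptide_frequencies)
  for (i in seq_len(n)) {
    for (j in i:n) {
      fi <- freqs[[i]]; fj <- freqs[[j]]
      common <- intersect(names(fi), names(fj))
      v <- if (length(common)) sum(fi[common] * fj[common]) * 100 else 0
      m[i, j] <- v; m[j, i] <- v
    }
  }
  class(m) <- c("pep_redundancy", "matrix", "array")
  m
}

#' Threshold summary of a redundancy matrix
#'
#' Counts mAbs whose best partner (diagonal excluded) strictly exceeds the
#' threshold, the per-pair count, and the maximal off-diagonal value with
#' the pair(s) attaining it.
#'
#' @param mat A [redundancy_matrix()].
#' @param threshold Percent threshold (default 40).
#' @return List: \code{n_mabs_over}, \code{n_pairs_over}, \code{max_value},
#'   \code{max_pairs} (data frame \code{mab_a}, \code{mab_b}),
#'   \code{mabs_over} (ids).
#' @export
summarize_redundancy <- function(mat, threshold = 40) {
  stopifnot(inherits(mat, "pep_redundancy") ||
              (is.matrix(mat) && nrow(mat) == ncol(mat)))
  off <- mat
  diag(off) <- -Inf
  best <- apply(off, 1, max)
  over <- best > threshold
  ut <- upper.tri(mat)
  n_pairs_over <- sum(off[ut] > threshold)
  max_value <- max(off[ut])
  hits <- which(off == max_value & ut, arr.ind = TRUE)
  max_pairs <- data.frame(mab_a = rownames(mat)[hits[, 1]],
                          mab_b = colnames(mat)[hits[, 2]],
                          stringsAsFactors = FALSE)
  list(n_mabs_over = sum(over), n_pairs_over = n_pairs_over,
       max_value = max_value, max_pairs = max_pairs,
       mabs_over = rownames(mat)[over])
}

#' Generate synthetic mimotope peptide sets with planted redundancy
#'
#' Each mAb receives \code{clones_per_mab} clones over a small number of
#' unique random peptides (uniform over the 20-residue alphabet, shared
#' peptides copied verbatim between pair members). For each planted pair
#' with target shared fraction \code{s}, both members devote
#' \code{round(s * clones_per_mab)} clones to one common peptide, the rest
#' to private singleton peptides, so the resulting redundancy is
#' approximately \code{s^2 * 100}.
#'
#' @param n_mabs Number of mAbs.
#' @param pairs Data frame with columns \code{mab_a}, \code{mab_b},
#'   \code{shared} (target shared fraction in [0, 1]), or \code{NULL}.
#' @param clones_per_mab Clones sequenced per mAb (>= 12).
#' @param peptide_length Peptide length in residues (default 12).
#' @param seed Integer seed.
#' @return Peptide table: \code{mab_id}, \code{peptide}, \code{count}.
#' @export
generate_mimotope_sets <- function(n_mabs, pairs = NULL, clones_per_mab = 12L,
                                   peptide_length = 12L, seed = 1L) {
  stopifnot(n_mabs >= 1, clones_per_mab >= 12, peptide_length >= 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mab_ids <- sprintf("mab_%03d", seq_len(n_mabs))
  if (!is.null(pairs)) {
    stopifnot(all(c("mab_a", "mab_b", "shared") %in% names(pairs)),
              all(pairs$shared >= 0 & pairs$shared <= 1))
    bad <- setdiff(c(pairs$mab_a, pairs$mab_b), mab_ids)
    if (length(bad)) stop("unknown mAb id(s) in pairs: ",
                          paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    rand_pep <- function(k)
      vapply(seq_len(k), function(i)
        paste(sample(aa, peptide_length, replace = TRUE), collapse = ""),
        character(1))
    tabs <- lapply(mab_ids, function(id) {
      # unpaired default: 1-3 unique peptides, counts summing to clones_per_mab
      k <- sample(1:3, 1)
      cnt <- as.vector(stats::rmultinom(1, clones_per_mab - k, rep(1, k))) + 1L
      data.frame(mab_id = id, peptide = rand_pep(k), count = cnt,
                 stringsAsFactors = FALSE)
    })
    names(tabs) <- mab_ids
    if (!is.null(pairs)) {
      for (i in seq_len(nrow(pairs))) {
        s <- pairs$shared[i]
        k_shared <- round(s * clones_per_mab)
        shared_pep <- rand_pep(1)
        for (id in c(pairs$mab_a[i], pairs$mab_b[i])) {
          n_priv <- clones_per_mab - k_shared
          parts <- list()
          if (k_shared > 0)
            parts$shared <- data.frame(mab_id = id, peptide = shared_pep,
                                       count = k_shared,
                                       stringsAsFactors = FALSE)
          if (n_priv > 0)
            parts$priv <- data.frame(mab_id = id, peptide = rand_pep(n_priv),
                                     count = 1L, stringsAsFactors = FALSE)
          tabs[[id]] <- do.call(rbind, parts)
        }
      }
    }
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  })
}

#' Build mimotope sets from a peptide table
#'
#' @param peptides Data frame \code{mab_id}, \code{peptide}, \code{count}
#'   (count defaults to 1 when the column is absent).
#' @return Named list of [mimotope_set()] objects.
#' @export
peptide_table_to_sets <- function(peptides) {
  stopifnot(all(c("mab_id", "peptide") %in% names(peptides)))
  if (!"count" %in% names(peptides)) peptides$count <- 1L
  sets <- lapply(split(peptides, peptides$mab_id), function(g)
    mimotope_set(g$mab_id[1],
                 stats::setNames(g$count, g$peptide)))
  sets[order(names(sets))]
}

#' Read mimotope peptides from TSV or FASTA
#'
#' TSV files carry columns \code{mab_id}, \code{peptide} and optionally
#' \code{count} (missing counts default to 1). FASTA files use headers of
#' the form \code{>mabID|cloneN}; every record counts as one clone.
#' Sequences are uppercased on read; non-amino-acid characters raise an
#' error naming the record.
#'
#' @param path File path; format chosen by extension
#'   (\code{.fasta}/\code{.fa} vs anything else = TSV).
#' @return Named list of [mimotope_set()] objects.
#' @export
read_peptides <- function(path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    mab <- sub("\\|.*$", "", names(seqs))
    tab <- data.frame(mab_id = mab,
                      peptide = toupper(as.character(seqs)),
                      count = 1L, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("mab_id", "peptide") %in% names(tab)))
      stop("peptide TSV needs columns mab_id, peptide")
    if (!"count" %in% names(tab)) tab$count <- 1L
    tab$peptide <- toupper(tab$peptide)
  }
  peptide_table_to_sets(tab)
}

#' Write a peptide table or redundancy matrix to TSV
#'
#' @param sets Named list of [mimotope_set()] objects.
#' @param path Output file.
#' @export
write_peptides <- function(sets, path) {
  tab <- do.call(rbind, lapply(sets, function(s)
    data.frame(mab_id = s$mab_id, peptide = names(s$counts),
               count = as.integer(s$counts), stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peptides
#' @param mat A [redundancy_matrix()].
#' @export
write_redundancy <- function(mat, path) {
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  tab <- data.frame(mab_a = rownames(mat)[idx[, 1]],
                    mab_b = colnames(mat)[idx[, 2]],
                    red_percent = mat[idx], stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
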