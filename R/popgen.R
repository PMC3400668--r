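# Kimura two-parameter (K2P) pairwise distances and within/between
# group summaries from aligned nucleotide sequences. Sequences are held
# as character strings over {A, C, G, T, -, N}; sites with a gap or
# ambiguity in either member of a pair are excluded (pairwise deletion).

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

seq_to_chars <- function(s) {
  if (length(s) == 1L && is.character(s)) {
    toupper(strsplit(s, "")[[1L]])
  } else {
    toupper(as.character(s))
  }
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Transition (`P`) and transversion (`Q`) proportions are counted over
#' sites where both sequences carry an unambiguous base; the distance is
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` substitutions per
#' site. Saturated pairs (either logarithm argument non-positive) raise
#' an error of class `swimphys_saturation`.
#'
#' @param seq1,seq2 Aligned sequences of equal length, as single strings
#'   or character vectors over `A C G T - N`.
#' @return List with `d`, `P`, `Q`, `valid_sites`.
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
#' k2p_distance(a, b)$d  # -0.5 * log(0.8)
#' @export
k2p_distance <- function(seq1, seq2) {
  a <- seq_to_chars(seq1); b <- seq_to_chars(seq2)
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  bases <- c(PURINES, PYRIMIDINES)
  valid <- a %in% bases & b %in% bases
  nv <- sum(valid)
  if (nv == 0L) stop("no valid sites after pairwise deletion",
                     call. = FALSE)
  a <- a[valid]; b <- b[valid]
  diff <- a != b
  ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- sum(ts) / nv
  Q <- sum(diff & !ts) / nv
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    stop(structure(
      class = c("swimphys_saturation", "error", "condition"),
      list(message = "substitution saturation: K2P distance undefined",
           call = NULL)))
  }
  list(d = -0.5 * log(arg1) - 0.25 * log(arg2), P = P, Q = Q,
       valid_sites = nv)
}

#' Pairwise K2P distance matrix
#'
#' All n(n-1)/2 distances of an alignment. Saturated pairs are recorded
#' as `NA` with a warning rather than aborting the matrix.
#'
#' @param sequences Named character vector of aligned sequences (or an
#'   `aligned_sequences` object from [gen_sequences()]).
#' @return Symmetric matrix of class `dist_k2p` with zero diagonal.
#' @export
pairwise_matrix <- function(sequences) {
  if (is.list(sequences) && !is.null(sequences$sequences)) {
    sequences <- sequences$sequences
  }
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(sequences) %||% sprintf("seq%03d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(k2p_distance(sequences[[i]], sequences[[j]])$d,
                      swimphys_saturation = function(e) {
                        n_sat <<- n_sat + 1L
                        NA_real_
                      })
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (n_sat > 0L) {
    warning(sprintf("%d saturated pair(s) recorded as NA", n_sat),
            call. = FALSE)
  }
  structure(d, class = c("dist_k2p", "matrix"))
}

#' Within-group and overall distance summaries
#'
#' @param dm Square distance matrix (e.g. from [pairwise_matrix()]).
#' @param groups Group label per sequence, in matrix order.
#' @return List with `within` (data frame: group, n, mean_distance —
#'   `NA` for singleton groups), `between_mean` (mean over pairs in
#'   different groups), and `overall` (mean, min, max over all pairs).
#' @export
group_mean_distances <- function(dm, groups) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (length(groups) != n) {
    stop("`groups` must label every sequence", call. = FALSE)
  }
  groups <- as.character(groups)
  pairs_i <- which(upper.tri(dm), arr.ind = TRUE)
  dvals <- dm[upper.tri(dm)]
  same <- groups[pairs_i[, 1L]] == groups[pairs_i[, 2L]]
  lv <- unique(groups)
  within <- data.frame(
    group = lv,
    n = as.integer(table(factor(groups, levels = lv))),
    mean_distance = vapply(lv, function(g) {
      sel <- same & groups[pairs_i[, 1L]] == g
      if (!any(sel)) NA_real_ else mean(dvals[sel], na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL
  )
  list(
    within = within,
    between_mean = if (any(!same)) mean(dvals[!same], na.rm = TRUE)
      else NA_real_,
    overall = c(mean = mean(dvals, na.rm = TRUE),
                min = min(dvals, na.rm = TRUE),
                max = max(dvals, na.rm = TRUE))
  )
}

#' Write a distance matrix as TSV
#'
#' @param dm Square matrix.
#' @param path Output path.
#' @param phylip Also write a PHYLIP-style lower-triangular matrix to
#'   `paste0(path, ".phy")`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, phylip = FALSE) {
  dm <- as.matrix(dm)
  utils::write.table(data.frame(id = rownames(dm), dm,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (phylip) {
    con <- file(paste0(path, ".phy"), "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(c(formatC(rownames(dm)[i], width = -10),
                         sprintf("%.6f", dm[i, seq_len(i - 1)])),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write aligned sequences as FASTA
#'
#' @param sequences Named character vector of sequences, or an
#'   `aligned_sequences` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.list(sequences) && !is.null(sequences$sequences)) {
    sequences <- sequences$sequences
  }
  ids <- names(sequences) %||% sprintf("seq%03d", seq_along(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(sequences[[i]], con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of equal-length sequences.
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("not a FASTA file", call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- ids
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  toupper(seqs)
}
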