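BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' Stores base probabilities per position (pseudocount-regularized),
#' background frequencies, per-position information content, and the
#' information-content-weighted log-odds score matrix used for motif
#' matching. The per-position score of base `b` is
#' `IC_i * log2(p_i(b) / bg(b))`; relative scores rescale the summed
#' score to [0, 1] against the minimum and maximum attainable values so
#' that the consensus scores exactly 1 and the anti-consensus exactly 0.
#'
#' @param mat 4 x L matrix of counts or probabilities, rows A, C, G, T.
#' @param tf_name factor name.
#' @param bg background base frequencies (length 4, sums to 1).
#' @param pseudocount added to each probability before normalization.
#' @return object of class `pwm`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0), 4, 6)  # poly-A motif
#' pwm(m, "polyA")$consensus
#' @export
pwm <- function(mat, tf_name = "TF", bg = rep(0.25, 4),
                pseudocount = 0.01) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4, all(mat >= 0),
            length(bg) == 4, abs(sum(bg) - 1) < 1e-9)
  rownames(mat) <- BASES
  prob <- sweep(mat, 2L, colSums(mat), `/`)
  prob <- sweep(prob + pseudocount, 2L, colSums(prob + pseudocount), `/`)
  if (any(abs(colSums(prob) - 1) > 1e-9)) stop("column normalization failed")
  ic <- 2 + colSums(prob * log2(prob))
  score <- sweep(log2(sweep(prob, 1L, bg, `/`)), 2L, ic, `*`)
  smin <- sum(apply(score, 2L, min))
  smax <- sum(apply(score, 2L, max))
  structure(list(
    tf_name = tf_name, prob = prob, bg = bg, ic = ic,
    score = score, score_min = smin, score_max = smax,
    length = ncol(prob),
    consensus = paste(BASES[apply(prob, 2L, which.max)], collapse = "")
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: length %d, consensus %s, total IC %.2f bits\n",
              x$tf_name, x$length, x$consensus, sum(x$ic)))
  invisible(x)
}

#' Read position weight matrices from JASPAR-style text
#'
#' Parses the four-row `A [ ... ]` count format (header lines start
#' with `>`).
#'
#' @param path file path.
#' @param ... passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    nm <- sub("^>\\s*\\S*\\s*", "", lines[h])
    if (!nzchar(nm)) nm <- sub("^>\\s*", "", lines[h])
    rows <- lines[h + 1:4]
    vals <- lapply(rows, function(r) {
      as.numeric(strsplit(gsub("^[ACGT]\\s*\\[|\\]", "", r),
                          "\\s+")[[1]] |> (\(z) z[nzchar(z)])())
    })
    out[[nm]] <- pwm(do.call(rbind, vals), tf_name = nm, ...)
  }
  out
}

#' Write position weight matrices as JASPAR-style text
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @param counts_scale probabilities are written as pseudo-counts scaled
#'   by this factor.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path, counts_scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    writeLines(sprintf(">%s %s", nm, p$tf_name), con)
    cnt <- round(p$prob * counts_scale)
    for (b in seq_len(4)) {
      writeLines(sprintf("%s [ %s ]", BASES[b],
                         paste(cnt[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

# internal: reverse complement of an upper-case DNA string (N allowed)
revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# internal: raw IC-weighted log-odds score of one k-mer (character vector);
# "N" scores as the background-weighted average of the position's scores
kmer_score <- function(p, kmer) {
  s <- 0
  for (i in seq_along(kmer)) {
    b <- kmer[i]
    s <- s + if (b == "N") sum(p$bg * p$score[, i]) else p$score[b, i]
  }
  s
}

#' Exact p-value of a relative motif score under the background model
#'
#' Probability that a random sequence drawn from the background base
#' frequencies attains a relative score at least as large as `rel`.
#' For motifs up to `exact_max_len` positions the full attainable-score
#' distribution is built by dynamic programming over positions on the
#' exact support (outer sums with deduplication); longer motifs fall
#' back to a lattice-discretized DP (granularity `1e-4` of the score
#' range), which is approximate near ties.
#'
#' @param p a `pwm`.
#' @param rel relative score in [0, 1].
#' @param exact_max_len longest motif handled exactly.
#' @return the match p-value.
#' @export
pwm_match_pvalue <- function(p, rel, exact_max_len = 10L) {
  stopifnot(inherits(p, "pwm"))
  thr_raw <- p$score_min + rel * (p$score_max - p$score_min)
  if (p$length <= exact_max_len) {
    scores <- 0
    probs <- 1
    for (i in seq_len(p$length)) {
      scores <- as.vector(outer(scores, p$score[, i], `+`))
      probs <- as.vector(outer(probs, p$bg, `*`))
      o <- order(scores)
      scores <- scores[o]
      probs <- probs[o]
      dup <- c(diff(scores) < 1e-12, FALSE)
      if (any(dup)) {
        grp <- cumsum(!c(FALSE, dup[-length(dup)]))
        probs <- as.vector(rowsum(probs, grp))
        scores <- scores[!c(FALSE, dup[-length(dup)])]
      }
    }
    sum(probs[scores >= thr_raw - 1e-9])
  } else {
    g <- (p$score_max - p$score_min) / (p$length * 1e4)
    qs <- round((p$score - p$score_min / p$length) / g)
    width <- sum(apply(qs, 2L, max)) + 1L
    dist <- numeric(width)
    dist[1L] <- 1
    for (i in seq_len(p$length)) {
      nd <- numeric(width)
      for (b in seq_len(4)) {
        sh <- qs[b, i]
        idx <- seq_len(width - sh)
        nd[idx + sh] <- nd[idx + sh] + dist[idx] * p$bg[b]
      }
      dist <- nd
    }
    thr_idx <- ceiling((thr_raw - p$score_min) / g - 1e-9)
    sum(dist[(max(thr_idx, 0) + 1L):width])
  }
}

#' Best motif match for one allele at a variant
#'
#' Substitutes `allele_base` at `variant_offset` (1-based within the
#' window), then scores every motif placement that covers the variant on
#' both strands and returns the best relative score, the strand, the
#' variant's offset within the motif, and the exact match p-value of the
#' best score.
#'
#' @param p a `pwm`.
#' @param window upper-case DNA string (A/C/G/T/N).
#' @param allele_base base substituted at the variant.
#' @param variant_offset 1-based position of the variant in `window`.
#' @return list: `score` (relative, in [0, 1]), `strand` ("+"/"-"),
#'   `motif_offset` (position of the variant within the motif, 1-based,
#'   on the matched strand), `match_p`.
#' @examples
#' m <- pwm(matrix(c(9, 1, 1, 1), 4, 6), "polyA")
#' score_allele(m, "TTTAAAAAATTT", "A", 6)$score
#' @export
score_allele <- function(p, window, allele_base, variant_offset) {
  stopifnot(inherits(p, "pwm"))
  if (!allele_base %in% c(BASES, "N")) {
    stop("allele base must be one of A, C, G, T (or N)")
  }
  chars <- strsplit(toupper(window), "")[[1]]
  if (variant_offset < 1 || variant_offset > length(chars)) {
    stop("variant offset outside the window")
  }
  if (!all(chars %in% c(BASES, "N"))) stop("window contains non-DNA bases")
  chars[variant_offset] <- allele_base
  L <- p$length
  W <- length(chars)
  if (W < L) stop("window shorter than the motif")

  best <- list(raw = -Inf, strand = NA_character_, motif_offset = NA_integer_)
  scan <- function(seq_chars, offset, strand) {
    starts <- max(1L, offset - L + 1L):min(offset, W - L + 1L)
    for (t in starts) {
      s <- kmer_score(p, seq_chars[t:(t + L - 1L)])
      if (s > best$raw) {
        best <<- list(raw = s, strand = strand,
                      motif_offset = offset - t + 1L)
      }
    }
  }
  scan(chars, variant_offset, "+")
  rc <- strsplit(revcomp(paste(chars, collapse = "")), "")[[1]]
  scan(rc, W - variant_offset + 1L, "-")

  rel <- (best$raw - p$score_min) / (p$score_max - p$score_min)
  rel <- min(max(rel, 0), 1)
  list(score = rel, strand = best$strand,
       motif_offset = best$motif_offset,
       match_p = pwm_match_pvalue(p, rel))
}
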