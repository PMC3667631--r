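#' Rank values within one replicate
#'
#' Ranks a replicate's b-scores (or any finite vector) with average ranks
#' for ties. `ascending` puts rank 1 on the most negative value (the
#' strongest hyposecretory candidate); `descending` on the largest.
#'
#' @param values finite numeric vector.
#' @param direction `"ascending"` or `"descending"`.
#' @return numeric rank vector in `[1, length(values)]`.
#' @export
rank_within_replicate <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (length(values) < 1L) stop("empty value vector", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite values cannot be ranked", call. = FALSE)
  v <- if (direction == "ascending") values else -values
  rank(v, ties.method = "average")
}

#' Rank product (geometric mean of ranks)
#'
#' @param ranks numeric vector of K ranks, all >= 1.
#' @return `(prod(ranks))^(1/K)`, computed on the log scale.
#' @export
rank_product <- function(ranks) {
  if (length(ranks) < 1L) stop("empty rank vector", call. = FALSE)
  if (any(!is.finite(ranks)) || any(ranks < 1))
    stop("ranks must be finite and >= 1", call. = FALSE)
  exp(mean(log(ranks)))
}

#' Permutation p-values and expected false-positive proportions
#'
#' Null distribution for rank products: each permutation draws K
#' independent uniform permutations of `1..n_genes` (one per replicate) and
#' computes all `n_genes` rank products, exactly mirroring the observed
#' statistic. The p-value counts how often a permuted rank product is at
#' least as small as the observed one, with the standard add-one correction
#' so the best attainable statistic never gets p = 0:
#' `p = (count + 1) / (n_perm * n_genes + 1)`.
#' The expected false-positive proportion is `pfp = p * n_genes / rank`,
#' where `rank` orders genes by their observed rank product.
#'
#' @param rp_observed observed per-gene rank products, in `[1, n_genes]`.
#' @param n_genes number of genes ranked in each replicate.
#' @param K number of replicates.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; fixed seed gives bit-identical p-values.
#' @return data.frame `p`, `pfp` aligned with `rp_observed`.
#' @export
permutation_pvalue <- function(rp_observed, n_genes, K, n_perm = 100L, seed = 1L) {
  n_genes <- as.integer(n_genes); K <- as.integer(K); n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L, K >= 1L, n_genes >= 1L)
  if (as.double(n_perm) * n_genes > 2^31 - 1)
    stop("n_perm * n_genes too large", call. = FALSE)
  if (any(rp_observed < 1 - 1e-9 | rp_observed > n_genes + 1e-9))
    stop("rank products must lie in [1, n_genes]", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  perm_rp <- numeric(n_perm * n_genes)
  for (b in seq_len(n_perm)) {
    lg <- matrix(0, n_genes, K)
    for (k in seq_len(K)) lg[, k] <- log(sample.int(n_genes))
    perm_rp[(b - 1L) * n_genes + seq_len(n_genes)] <- exp(rowMeans(lg))
  }
  perm_rp <- sort(perm_rp)
  # count of permuted rank products <= observed; nudge guards against
  # representation noise in exp(mean(log(.))) between identical rank sets
  cnt <- findInterval(rp_observed * (1 + 1e-12), perm_rp)
  p <- (cnt + 1) / (n_perm * n_genes + 1)
  rk <- rank(rp_observed, ties.method = "average")
  data.frame(p = p, pfp = p * n_genes / rk)
}

#' Rank-product table for a screen
#'
#' Aggregates per-replicate b-score rankings into rank products per gene,
#' for both tails (down = hyposecretory candidates, up = hypersecretory),
#' with permutation p-values and expected false-positive proportions. The
#' two tails are analysed separately because the screen classifies hits by
#' direction. Genes lacking a finite b-score in every replicate are dropped
#' with a warning (ranks are only comparable on a complete matrix).
#'
#' @param b_table B-score table from [b_score_screen()] (`gene_id`,
#'   `replicate`, `b_score`).
#' @param n_perm permutations for the null; see [permutation_pvalue()].
#' @param seed integer seed for the permutation null.
#' @return data.frame `gene_id`, `rp_down`, `rp_up`, `p_down`, `p_up`,
#'   `pfp_down`, `pfp_up`, plus matrices of per-replicate ranks as
#'   attributes `ranks_down`, `ranks_up`.
#' @export
rank_product_table <- function(b_table, n_perm = 100L, seed = 1L) {
  stopifnot(all(c("gene_id", "replicate", "b_score") %in% names(b_table)))
  reps <- sort(unique(b_table$replicate))
  genes <- sort(unique(b_table$gene_id))
  m <- matrix(NA_real_, length(genes), length(reps),
              dimnames = list(genes, reps))
  m[cbind(match(b_table$gene_id, genes), match(b_table$replicate, reps))] <-
    b_table$b_score
  ok <- rowSums(!is.finite(m)) == 0L
  if (any(!ok))
    warning(sum(!ok), " gene(s) without a full set of finite b-scores ",
            "dropped from rank-product analysis")
  m <- m[ok, , drop = FALSE]
  n <- nrow(m); K <- ncol(m)
  if (n < 1L) stop("no genes with complete b-scores", call. = FALSE)
  rdown <- apply(m, 2L, rank_within_replicate, direction = "ascending")
  rup <- apply(m, 2L, rank_within_replicate, direction = "descending")
  rp_down <- exp(rowMeans(log(rdown)))
  rp_up <- exp(rowMeans(log(rup)))
  pd <- permutation_pvalue(rp_down, n, K, n_perm = n_perm, seed = seed)
  pu <- permutation_pvalue(rp_up, n, K, n_perm = n_perm, seed = seed + 1L)
  out <- data.frame(gene_id = rownames(m),
                    rp_down = rp_down, rp_up = rp_up,
                    p_down = pd$p, p_up = pu$p,
                    pfp_down = pd$pfp, pfp_up = pu$pfp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ranks_down") <- rdown
  attr(out, "ranks_up") <- rup
  out
}
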