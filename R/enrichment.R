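# Composition-Profiler-style enrichment: fractional difference of amino-acid
# frequencies between a query and a background residue pool, with a bootstrap
# standard error, a two-sided z-test and Bonferroni correction; the same
# machinery drives composition-weighted residue-property comparisons.

#' Pool window residues into a composition profile
#'
#' Concatenates window residues into one pool and tabulates amino-acid
#' fractions. `X` (unknown) residues are dropped with a message.
#'
#' @param windows A window tibble (with a `residues` column) or a character
#'   vector of sequences/residues.
#' @return A `composition_profile` tibble with `aa`, `count`, `fraction`
#'   (rows cover all 20 standard residues) and attribute `total`.
#' @export
pool_residues <- function(windows) {
  seqs <- if (is.data.frame(windows)) windows$residues else windows
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) abort("Empty residue pool")
  res <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  n_x <- sum(!res %in% AA20)
  if (n_x > 0L) {
    inform(paste0("Dropped ", n_x, " non-standard residue(s) from the pool"))
    res <- res[res %in% AA20]
  }
  if (length(res) == 0L) abort("Empty residue pool after dropping non-standard residues")
  composition_profile(res)
}

# Profile from a character vector of single residues (assumed standard).
composition_profile <- function(residues) {
  counts <- table(factor(residues, levels = AA20))
  out <- tibble(aa = AA20, count = as.integer(counts),
                fraction = as.integer(counts) / length(residues))
  attr(out, "total") <- length(residues)
  class(out) <- c("composition_profile", class(out))
  out
}

#' Fractional difference between two composition profiles
#'
#' For each amino acid, `D(a) = (Cq(a) - Cb(a)) / Cb(a)`: the relative
#' enrichment of the query pool over the background pool. `D` is `NA` when
#' the background fraction is zero but the query fraction is not, and `0`
#' when both are zero.
#'
#' @param query,background `composition_profile` tibbles (see
#'   [pool_residues()]).
#' @return A tibble with `aa`, `c_query`, `c_background`, `d`.
#' @export
fractional_difference <- function(query, background) {
  cq <- query$fraction[match(AA20, query$aa)]
  cb <- background$fraction[match(AA20, background$aa)]
  d <- (cq - cb) / cb
  d[cb == 0 & cq == 0] <- 0
  d[cb == 0 & cq > 0] <- NA_real_
  tibble(aa = AA20, c_query = cq, c_background = cb, d = d)
}

# iterations x 20 matrix of resampled fractions: bootstrap of drawing `size`
# residues with replacement from a pool with composition `prob`, done as
# multinomial draws for speed.
boot_fractions <- function(prob, size, iterations) {
  m <- rmultinom(iterations, size, prob)  # 20 x iterations
  t(m) / size
}

#' Bootstrap amino-acid enrichment between two residue pools
#'
#' Computes the observed fractional difference `D(a)` per amino acid and, by
#' resampling both pools with replacement at their observed sizes for
#' `iterations` rounds, a bootstrap standard error. Two-sided p-values come
#' from the z-score `D / SE` against the standard normal; the significance
#' flag applies a Bonferroni factor of 20 (one per amino acid).
#'
#' @param query_pool,background_pool Character vectors of residues or window
#'   sequences (pooled via [pool_residues()]), or `composition_profile`
#'   tibbles.
#' @param iterations Bootstrap iterations (default 10000; at least 100).
#' @param alpha Family significance level before correction (default 0.05).
#' @param seed Integer seed for reproducible resampling.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return A `glyco_enrichment` tibble with `aa`, `c_query`, `c_background`,
#'   `d`, `se`, `p_value`, `significant`, `direction`
#'   (`enriched`/`depleted`/`ns`). Attributes record `iterations`, `alpha`,
#'   `correction` and the two pool sizes.
#' @export
bootstrap_enrichment <- function(query_pool, background_pool, iterations = 10000L,
                                 alpha = 0.05, seed = NULL,
                                 correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(iterations >= 100L, alpha > 0, alpha < 1)
  q <- as_profile(query_pool)
  b <- as_profile(background_pool)
  nq <- attr(q, "total")
  nb <- attr(b, "total")
  if (min(nq, nb) < 20L) {
    warn("Residue pool smaller than 20; bootstrap standard errors are unstable")
  }
  obs <- fractional_difference(q, b)
  with_seed(seed, {
    fq <- boot_fractions(q$fraction, nq, iterations)
    fb <- boot_fractions(b$fraction, nb, iterations)
    db <- (fq - fb) / fb
    db[!is.finite(db)] <- NA
    se <- apply(db, 2L, sd, na.rm = TRUE)
    out <- enrichment_result(obs, se, alpha,
                             divisor = if (correction == "bonferroni") 20L else 1L)
    attr(out, "iterations") <- iterations
    attr(out, "alpha") <- alpha
    attr(out, "correction") <- correction
    attr(out, "n_query") <- nq
    attr(out, "n_background") <- nb
    class(out) <- c("glyco_enrichment", class(out))
    out
  })
}

as_profile <- function(x) {
  if (inherits(x, "composition_profile")) x else pool_residues(x)
}

enrichment_result <- function(obs, se, alpha, divisor) {
  z <- obs$d / se
  p <- 2 * pnorm(-abs(z))
  p[!is.na(obs$d) & obs$d == 0 & (is.na(se) | se == 0)] <- 1
  p[is.na(obs$d)] <- NA_real_
  sig <- !is.na(p) & p <= alpha / divisor
  dplyr::mutate(
    obs,
    se = se,
    p_value = p,
    significant = sig,
    direction = dplyr::case_when(
      !sig ~ "ns",
      d > 0 ~ "enriched",
      d < 0 ~ "depleted",
      .default = "ns"
    )
  )
}

#' Label-permutation p-values for amino-acid enrichment
#'
#' Independent cross-check of [bootstrap_enrichment()]: residues of the two
#' pools are pooled and the query/background labels permuted; the two-sided
#' p-value per amino acid is the fraction of permutations with `|D|` at least
#' the observed one.
#'
#' @inheritParams bootstrap_enrichment
#' @param n_perm Number of permutations.
#' @return A tibble with `aa`, `d`, `p_value`.
#' @export
permutation_enrichment <- function(query_pool, background_pool, n_perm = 1000L,
                                   seed = NULL) {
  q <- as_profile(query_pool)
  b <- as_profile(background_pool)
  nq <- attr(q, "total")
  nb <- attr(b, "total")
  obs <- fractional_difference(q, b)
  pooled_counts <- q$count + b$count
  pooled <- rep(AA20, pooled_counts)
  with_seed(seed, {
    exceed <- matrix(0L, nrow = n_perm, ncol = 20L)
    for (r in seq_len(n_perm)) {
      lab <- sample.int(nq + nb) <= nq
      cq <- tabulate(factor(pooled[lab], levels = AA20), 20L) / nq
      cb <- tabulate(factor(pooled[!lab], levels = AA20), 20L) / nb
      dperm <- (cq - cb) / cb
      exceed[r, ] <- as.integer(!is.na(dperm) & !is.na(obs$d) &
                                  abs(dperm) >= abs(obs$d))
    }
    tibble(aa = AA20, d = obs$d,
           p_value = (colSums(exceed) + 1L) / (n_perm + 1L))
  })
}

#' Bootstrap residue-property enrichment between two pools
#'
#' For each property scale, the composition-weighted mean scale value
#' `S = sum_a scale(a) * C(a)` is computed for the query and background pools
#' and their difference tested with the same multinomial bootstrap as
#' [bootstrap_enrichment()]. The Bonferroni divisor is the number of scales
#' tested.
#'
#' @inheritParams bootstrap_enrichment
#' @param scales A list of property scales as returned by [builtin_scales()].
#' @return A `glyco_property_enrichment` tibble with `scale`, `s_query`,
#'   `s_background`, `difference`, `se`, `p_value`, `significant`,
#'   `direction`.
#' @export
property_enrichment <- function(query_pool, background_pool,
                                scales = builtin_scales(), iterations = 10000L,
                                alpha = 0.05, seed = NULL,
                                correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(iterations >= 100L)
  q <- as_profile(query_pool)
  b <- as_profile(background_pool)
  nq <- attr(q, "total")
  nb <- attr(b, "total")
  smat <- vapply(scales, function(s) s$values[AA20], numeric(20L))  # 20 x nscales
  sq <- drop(crossprod(q$fraction, smat))
  sb <- drop(crossprod(b$fraction, smat))
  divisor <- if (correction == "bonferroni") length(scales) else 1L
  with_seed(seed, {
    fq <- boot_fractions(q$fraction, nq, iterations)   # iter x 20
    fb <- boot_fractions(b$fraction, nb, iterations)
    diffs <- (fq %*% smat) - (fb %*% smat)             # iter x nscales
    se <- apply(diffs, 2L, sd)
    diff_obs <- sq - sb
    z <- diff_obs / se
    p <- 2 * pnorm(-abs(z))
    p[diff_obs == 0 & se == 0] <- 1
    sig <- !is.na(p) & p <= alpha / divisor
    out <- tibble(
      scale = names(scales), s_query = unname(sq), s_background = unname(sb),
      difference = unname(diff_obs), se = unname(se), p_value = unname(p),
      significant = unname(sig),
      direction = dplyr::case_when(
        !sig ~ "ns", diff_obs > 0 ~ "enriched", .default = "depleted"
      )
    )
    attr(out, "iterations") <- iterations
    attr(out, "alpha") <- alpha
    attr(out, "correction") <- correction
    class(out) <- c("glyco_property_enrichment", class(out))
    out
  })
}
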