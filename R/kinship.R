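#' Pairwise relatedness estimators
#'
#' Moment estimators of pairwise relatedness r for diploid codominant data:
#' Queller-Goodnight (`QG`), Li's similarity estimator (`LynchLi`),
#' Lynch-Ritland (`LynchRd`), Ritland's kinship estimator (`Ritland`), and
#' the similarity-category moment estimator of Wang (`Wang`). All are
#' computed per locus from the published formulas and combined across loci
#' with each estimator's locus weighting; asymmetric estimators
#' (Queller-Goodnight, Lynch-Ritland) are symmetrised by averaging the two
#' reference directions. Loci with a vanishing denominator for a direction
#' are skipped for that direction.
#'
#' Moment estimators are unbiased but unbounded: estimates can fall outside
#' `[0, 1]`, especially for unrelated pairs at few loci.
#'
#' @param x,y [genotype_matrix()] objects with paired rows (pair i = row i
#'   of each) and identical loci.
#' @param freqs reference per-locus allele frequencies (list of named
#'   vectors, as from [allele_freqs()]).
#' @param estimator one of `"QG"`, `"LynchLi"`, `"LynchRd"`, `"Ritland"`,
#'   `"Wang"`.
#' @return Numeric vector of r estimates, one per pair (`NA` when no locus
#'   is co-typed).
#' @export
relatedness_moment <- function(x, y, freqs,
                               estimator = c("QG", "LynchLi", "LynchRd",
                                             "Ritland", "Wang")) {
  estimator <- match.arg(estimator)
  stopifnot(identical(x$loci, y$loci))
  parts <- .pair_parts(x, y, freqs)
  unname(switch(estimator,
                QG = .est_qg(parts),
                LynchLi = .est_lynchli(parts),
                LynchRd = .est_lynchrd(parts),
                Ritland = .est_ritland(parts),
                Wang = .est_wang(parts)))
}

# Precompute per-pair, per-locus building blocks shared by the estimators.
.pair_parts <- function(x, y, freqs) {
  L <- length(x$loci)
  n <- nrow(x$a1)
  freqs <- .check_freqs(freqs)
  lk <- function(codes, p) {
    out <- unname(p[as.character(codes)])
    if (anyNA(out[!is.na(codes)]))
      stop("allele missing from the reference frequency table")
    out
  }
  parts <- vector("list", L)
  for (j in seq_len(L)) {
    p <- freqs[[j]]
    xa <- x$a1[, j]; xb <- x$a2[, j]; ya <- y$a1[, j]; yb <- y$a2[, j]
    ok <- !is.na(xa) & !is.na(ya)
    parts[[j]] <- list(
      ok = ok,
      xa = xa, xb = xb, ya = ya, yb = yb,
      pa = lk(xa, p), pb = lk(xb, p), pc = lk(ya, p), pd = lk(yb, p),
      Sac = xa == ya, Sad = xa == yb, Sbc = xb == ya, Sbd = xb == yb,
      hx = xa != xb, hy = ya != yb,
      a2 = sum(p^2), a3 = sum(p^3), a4 = sum(p^4),
      k = length(p))
  }
  parts
}

.est_qg <- function(parts) {
  nx <- dx <- ny <- dy <- 0
  degen <- any_ok <- FALSE
  for (q in parts) {
    shared <- 0.5 * (q$Sac + q$Sad + q$Sbc + q$Sbd)
    numx <- shared - q$pa - q$pb
    denx <- 1 + (!q$hx) - q$pa - q$pb
    numy <- shared - q$pc - q$pd
    deny <- 1 + (!q$hy) - q$pc - q$pd
    usex <- q$ok & abs(denx) > 1e-12
    usey <- q$ok & abs(deny) > 1e-12
    nx <- nx + ifelse(usex, numx, 0); dx <- dx + ifelse(usex, denx, 0)
    ny <- ny + ifelse(usey, numy, 0); dy <- dy + ifelse(usey, deny, 0)
    # identical heterozygotes at a locus whose two alleles have total
    # frequency 1 give 0/0, but the formula's limit there is exactly 1
    degen <- degen | (q$ok & abs(denx) <= 1e-12 & abs(numx) <= 1e-12)
    any_ok <- any_ok | q$ok
  }
  rx <- ifelse(dx != 0, nx / dx, NA_real_)
  ry <- ifelse(dy != 0, ny / dy, NA_real_)
  out <- rowMeans(cbind(rx, ry), na.rm = TRUE)
  out[is.nan(out) & degen & any_ok] <- 1
  out
}

.est_lynchli <- function(parts) {
  num <- den <- 0
  for (q in parts) {
    S <- 0.25 * ((q$Sac | q$Sad) + (q$Sbc | q$Sbd) +
                 (q$Sac | q$Sbc) + (q$Sad | q$Sbd))
    S0 <- 2 * q$a2 - q$a3
    num <- num + ifelse(q$ok, S - S0, 0)
    den <- den + ifelse(q$ok, 1 - S0, 0)
  }
  ifelse(den != 0, num / den, NA_real_)
}

.est_lynchrd <- function(parts) {
  nx <- wx <- ny <- wy <- 0
  for (q in parts) {
    numx <- q$pa * (q$Sbc + q$Sbd) + q$pb * (q$Sac + q$Sad) -
      4 * q$pa * q$pb
    denx <- (1 + (!q$hx)) * (q$pa + q$pb) - 4 * q$pa * q$pb
    numy <- q$pc * (q$Sad + q$Sbd) + q$pd * (q$Sac + q$Sbc) -
      4 * q$pc * q$pd
    deny <- (1 + (!q$hy)) * (q$pc + q$pd) - 4 * q$pc * q$pd
    usex <- q$ok & abs(denx) > 1e-12
    usey <- q$ok & abs(deny) > 1e-12
    # weighted multi-locus form: weight W_l = den / (2 pa pb), and
    # W_l * r_l = num / (2 pa pb)
    nx <- nx + ifelse(usex, numx / (2 * q$pa * q$pb), 0)
    wx <- wx + ifelse(usex, denx / (2 * q$pa * q$pb), 0)
    ny <- ny + ifelse(usey, numy / (2 * q$pc * q$pd), 0)
    wy <- wy + ifelse(usey, deny / (2 * q$pc * q$pd), 0)
  }
  rx <- ifelse(wx != 0, nx / wx, NA_real_)
  ry <- ifelse(wy != 0, ny / wy, NA_real_)
  rowMeans(cbind(rx, ry), na.rm = TRUE)
}

.est_ritland <- function(parts) {
  num <- den <- 0
  for (q in parts) {
    if (q$k < 2L) next
    s <- 0.25 * (q$Sac / q$pa + q$Sad / q$pa + q$Sbc / q$pb + q$Sbd / q$pb)
    num <- num + ifelse(q$ok, 2 * (s - 1), 0)
    den <- den + ifelse(q$ok, q$k - 1, 0)
  }
  ifelse(den != 0, num / den, NA_real_)
}

# Wang-type estimator: the pair's similarity category at each locus
# (1 identical, 2 hom-het sharing, 3 het-het sharing one, 4 no allele
# shared) has expectation linear in (phi, Delta) = (k1, k2); the system is
# solved by least squares across loci and r = phi/2 + Delta.
.est_wang <- function(parts) {
  n <- length(parts[[1]]$ok)
  M11 <- M12 <- M22 <- v1 <- v2 <- numeric(n)
  for (q in parts) {
    b <- 2 * q$a2^2 - q$a4
    d <- 4 * (q$a3 - q$a4)
    f <- 4 * (q$a2 - q$a2^2 - 2 * q$a3 + 2 * q$a4)
    X <- rbind(c(q$a2 - b, 1 - b),
               c(2 * (q$a2 - q$a3) - d, -d),
               c(1 - 3 * q$a2 + 2 * q$a3 - f, -f))
    cc <- c(b, d, f)
    XtX <- crossprod(X)
    cons <- -as.numeric(crossprod(X, cc))
    nshared <- q$Sac + q$Sad + q$Sbc + q$Sbd
    identical_g <- (q$xa == q$ya & q$xb == q$yb)
    cat <- integer(n)
    cat[identical_g] <- 1L
    homhet <- !identical_g & (q$hx != q$hy) & nshared > 0
    cat[homhet] <- 2L
    hethet1 <- !identical_g & q$hx & q$hy & nshared > 0
    cat[hethet1] <- 3L
    cat[nshared == 0] <- 4L
    cat[!identical_g & !q$hx & !q$hy & nshared > 0] <- 4L # impossible; guard
    ok <- q$ok
    M11[ok] <- M11[ok] + XtX[1, 1]
    M12[ok] <- M12[ok] + XtX[1, 2]
    M22[ok] <- M22[ok] + XtX[2, 2]
    Xz <- rbind(X, c(0, 0))  # category 4 contributes no indicator row
    v1[ok] <- v1[ok] + Xz[cat[ok], 1] + cons[1]
    v2[ok] <- v2[ok] + Xz[cat[ok], 2] + cons[2]
  }
  det <- M11 * M22 - M12^2
  phi <- (M22 * v1 - M12 * v2) / det
  delta <- (-M12 * v1 + M11 * v2) / det
  out <- phi / 2 + delta
  out[det == 0 | !is.finite(out)] <- NA_real_
  out
}

# ---------------------------------------------------------------------------
# Likelihood machinery: condensed identity (Jacquard) mode probabilities of
# an ordered pair of unordered genotypes. Columns are modes D1..D9; the
# non-inbred modes are D7 (both pairs IBD, k2), D8 (one pair, k1), D9 (none,
# k0). Each column sums to 1 over all genotype pairs (property-tested).
.jacquard_probs <- function(xa, xb, ya, yb, p) {
  n <- length(xa)
  P <- matrix(0, n, 9L)
  pa <- unname(p[as.character(xa)]); pb <- unname(p[as.character(xb)])
  pc <- unname(p[as.character(ya)]); pd <- unname(p[as.character(yb)])
  hx <- xa != xb; hy <- ya != yb
  for (i in seq_len(n)) {
    a <- xa[i]; b <- xb[i]; c <- ya[i]; d <- yb[i]
    Pa <- pa[i]; Pb <- pb[i]; Pc <- pc[i]; Pd <- pd[i]
    if (!hx[i] && !hy[i]) {
      if (a == c) {           # (aa, aa)
        P[i, ] <- c(Pa, Pa^2, Pa^2, Pa^3, Pa^2, Pa^3, Pa^2, Pa^3, Pa^4)
      } else {                # (aa, bb)
        P[i, ] <- c(0, Pa * Pc, 0, Pa * Pc^2, 0, Pa^2 * Pc, 0, 0,
                    Pa^2 * Pc^2)
      }
    } else if (!hx[i] && hy[i]) {
      if (a == c || a == d) { # (aa, ab)
        Po <- if (a == c) Pd else Pc   # y's other allele
        P[i, ] <- c(0, 0, Pa * Po, 2 * Pa^2 * Po, 0, 0, 0, Pa^2 * Po,
                    2 * Pa^3 * Po)
      } else {                # (aa, bc)
        P[i, ] <- c(0, 0, 0, 2 * Pa * Pc * Pd, 0, 0, 0, 0,
                    2 * Pa^2 * Pc * Pd)
      }
    } else if (hx[i] && !hy[i]) {
      if (c == a || c == b) { # (ab, aa)
        Po <- if (c == a) Pb else Pa
        P[i, ] <- c(0, 0, 0, 0, Pc * Po, 2 * Pc^2 * Po, 0, Pc^2 * Po,
                    2 * Pc^3 * Po)
      } else {                # (ab, cc)
        P[i, ] <- c(0, 0, 0, 0, 0, 2 * Pc * Pa * Pb, 0, 0,
                    2 * Pc^2 * Pa * Pb)
      }
    } else {
      same <- (a == c && b == d) || (a == d && b == c)
      if (same) {             # (ab, ab)
        P[i, ] <- c(0, 0, 0, 0, 0, 0, 2 * Pa * Pb,
                    Pa * Pb * (Pa + Pb), 4 * Pa^2 * Pb^2)
      } else {
        sh <- intersect(c(a, b), c(c, d))
        if (length(sh) == 1L) {  # (ab, ac)
          Ps <- unname(p[as.character(sh)])
          Pox <- if (a == sh) Pb else Pa
          Poy <- if (c == sh) Pd else Pc
          P[i, ] <- c(0, 0, 0, 0, 0, 0, 0, Ps * Pox * Poy,
                      4 * Ps^2 * Pox * Poy)
        } else {                 # (ab, cd)
          P[i, ] <- c(0, 0, 0, 0, 0, 0, 0, 0, 4 * Pa * Pb * Pc * Pd)
        }
      }
    }
  }
  P
}

#' Dyadic maximum-likelihood relatedness
#'
#' Models the genotype-pair likelihood per locus as a mixture over
#' identity-by-descent modes: the three non-inbred modes (k0, k1, k2) by
#' default, or the nine condensed Jacquard modes with
#' `allow_inbreeding = TRUE`. The mixture weights are maximised jointly
#' over loci by EM on the probability simplex (tolerance `1e-8` on the
#' log-likelihood, best of `n_starts` seeded starts);
#' `r = k1/2 + k2` (non-inbred) or `r = 2*Delta1 + Delta3 + Delta5 +
#' Delta7 + Delta8/2` (Jacquard). The estimate is bounded in `[0, 1]`.
#'
#' @inheritParams relatedness_moment
#' @param allow_inbreeding use the 9-mode Jacquard parameterisation.
#' @param n_starts number of EM starting points on the simplex.
#' @param max_iter EM iteration cap per start.
#' @return A data.frame with one row per pair: `r`, plus the fitted mode
#'   weights (`k0`,`k1`,`k2` or `d1`..`d9`) and `loglik`.
#' @export
relatedness_dyadml <- function(x, y, freqs, allow_inbreeding = FALSE,
                               n_starts = 5L, max_iter = 500L) {
  stopifnot(identical(x$loci, y$loci))
  freqs <- .check_freqs(freqs)
  n <- nrow(x$a1)
  L <- length(x$loci)
  n_modes <- if (allow_inbreeding) 9L else 3L
  # per-pair list of L x n_modes likelihood matrices
  A <- array(NA_real_, c(n, L, n_modes))
  for (j in seq_len(L)) {
    ok <- !is.na(x$a1[, j]) & !is.na(y$a1[, j])
    if (!any(ok)) next
    Pj <- .jacquard_probs(x$a1[ok, j], x$a2[ok, j],
                          y$a1[ok, j], y$a2[ok, j], freqs[[j]])
    if (allow_inbreeding) A[ok, j, ] <- Pj
    else A[ok, j, ] <- Pj[, c(9L, 8L, 7L), drop = FALSE]  # k0, k1, k2
  }
  # deterministic spread of starting points on the simplex
  starts <- .simplex_starts(n_modes, n_starts)
  out <- data.frame(r = numeric(n))
  W <- matrix(NA_real_, n, n_modes)
  ll <- numeric(n)
  for (i in seq_len(n)) {
    Ai <- A[i, , , drop = TRUE]
    if (L == 1L) Ai <- matrix(Ai, 1L, n_modes)
    Ai <- Ai[stats::complete.cases(Ai), , drop = FALSE]
    if (nrow(Ai) == 0L) { W[i, ] <- NA; ll[i] <- NA; next }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- .em_mixture(Ai, starts[s, ], max_iter = max_iter, tol = 1e-8)
      if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
    }
    W[i, ] <- best$w
    ll[i] <- best$loglik
  }
  if (allow_inbreeding) {
    colnames(W) <- paste0("d", 1:9)
    r <- 2 * W[, 1] + W[, 3] + W[, 5] + W[, 7] + W[, 8] / 2
  } else {
    colnames(W) <- c("k0", "k1", "k2")
    r <- W[, "k1"] / 2 + W[, "k2"]
  }
  cbind(data.frame(r = r), as.data.frame(W), loglik = ll)
}

.simplex_starts <- function(m, n_starts) {
  pts <- matrix(1 / m, 1L, m)
  if (n_starts > 1L) {
    extra <- diag(m) * 0.85 + (1 - 0.85) / m
    pts <- rbind(pts, extra)
  }
  pts[seq_len(min(n_starts, nrow(pts))), , drop = FALSE]
}

# EM for a finite mixture with fixed component likelihood columns
.em_mixture <- function(A, w, max_iter = 500L, tol = 1e-8) {
  if (any(rowSums(A) <= 0))
    stop("zero likelihood under all modes (check frequency table)")
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    num <- sweep(A, 2L, w, "*")
    rs <- rowSums(num)
    ll <- sum(log(rs))
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
    gamma <- num / rs
    w <- colMeans(gamma)
  }
  list(w = w, loglik = ll)
}

#' Maximum-likelihood relationship classification
#'
#' Evaluates the genotype-pair likelihood under the fixed IBD coefficients
#' of the four standard categories (U, HS, FS, PO) and returns the argmax,
#' breaking ties toward the less related category (conservative). A pair
#' sharing no allele at some locus has zero likelihood under PO (Mendelian
#' exclusion).
#'
#' @inheritParams relatedness_moment
#' @return A data.frame per pair: `category` (factor U/HS/FS/PO) and the
#'   log-likelihood of each category (`-Inf` where excluded).
#' @export
classify_relationship <- function(x, y, freqs) {
  stopifnot(identical(x$loci, y$loci))
  freqs <- .check_freqs(freqs)
  n <- nrow(x$a1)
  cats <- c("U", "HS", "FS", "PO")
  K <- rbind(U = c(1, 0, 0), HS = c(0.5, 0.5, 0),
             FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
  ll <- matrix(0, n, 4L, dimnames = list(NULL, cats))
  for (j in seq_along(x$loci)) {
    ok <- !is.na(x$a1[, j]) & !is.na(y$a1[, j])
    if (!any(ok)) next
    Pj <- .jacquard_probs(x$a1[ok, j], x$a2[ok, j],
                          y$a1[ok, j], y$a2[ok, j], freqs[[j]])
    A <- Pj[, c(9L, 8L, 7L), drop = FALSE]
    for (ct in seq_len(4L)) {
      lik <- as.numeric(A %*% K[ct, ])
      ll[ok, ct] <- ll[ok, ct] + ifelse(lik > 0, log(lik), -Inf)
    }
  }
  if (any(apply(ll, 1, function(z) all(is.infinite(z))))) {
    bad <- which(apply(ll, 1, function(z) all(is.infinite(z))))[1]
    stop("zero likelihood under all categories for pair ", bad,
         " (impossible genotypes given the frequency table)")
  }
  # argmax with conservative ties: categories ordered least related first,
  # and which.max takes the first maximum
  category <- apply(ll, 1, function(z) cats[which.max(z)])
  category <- factor(category, levels = cats)
  cbind(data.frame(category = category), as.data.frame(ll))
}

#' Simulation-based estimator evaluation
#'
#' Simulates `n_pairs` genotype pairs per relationship category with
#' [sim_pedigree_pairs()], computes every estimator on each pair, and
#' reports per-estimator means, sampling variances, inter-estimator
#' correlations, and the minimum-variance estimator.
#'
#' @param freqs per-locus allele frequency list.
#' @param n_pairs pairs per category.
#' @param categories character vector of category labels.
#' @param estimators which estimators to include (`"DyadML"` is the
#'   likelihood-based one and is substantially slower).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `summary` (data.frame: category, estimator, mean, var),
#'   `correlations` (by category), `recommended` (minimum mean sampling
#'   variance across categories), `estimates` (long data.frame).
#' @export
evaluate_estimators <- function(freqs, n_pairs = 5000L,
                                categories = c("U", "HS", "FS"),
                                estimators = c("QG", "LynchLi", "LynchRd",
                                               "Ritland", "Wang", "DyadML"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- .check_freqs(freqs)
  rows <- list(); cors <- list(); est_long <- list()
  for (cat in categories) {
    sim <- sim_pedigree_pairs(freqs, cat, n_pairs)
    vals <- list()
    for (est in estimators) {
      vals[[est]] <- if (est == "DyadML")
        relatedness_dyadml(sim$x, sim$y, freqs)$r
      else relatedness_moment(sim$x, sim$y, freqs, est)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, estimator = est,
        mean = mean(vals[[est]], na.rm = TRUE),
        var = stats::var(vals[[est]], na.rm = TRUE),
        stringsAsFactors = FALSE)
      est_long[[length(est_long) + 1L]] <- data.frame(
        category = cat, estimator = est, pair = seq_len(n_pairs),
        r = vals[[est]], stringsAsFactors = FALSE)
    }
    cors[[cat]] <- stats::cor(do.call(cbind, vals), use = "complete.obs")
  }
  summary <- do.call(rbind, rows)
  meanvar <- tapply(summary$var, summary$estimator, mean)
  list(summary = summary, correlations = cors,
       recommended = names(which.min(meanvar)),
       estimates = do.call(rbind, est_long))
}

#' All-pairs relatedness table for a sample
#'
#' Computes the requested estimators for every unordered pair of
#' individuals, using allele frequencies from the full sample (including
#' each focal pair) unless `freqs` is supplied.
#'
#' @param g a [genotype_matrix()].
#' @param estimators estimator names (see [evaluate_estimators()]).
#' @param freqs optional reference frequencies; default [allele_freqs()] of
#'   `g`.
#' @return A long data.frame: `id1`, `id2`, one column per estimator.
#' @export
pairwise_relatedness <- function(g, estimators = c("QG", "DyadML"),
                                 freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_freqs(g)
  pr <- utils::combn(length(g$ids), 2)
  # rows repeat individuals, so rebuild with synthetic unique row IDs
  x <- genotype_matrix(g$a1[pr[1, ], , drop = FALSE],
                       g$a2[pr[1, ], , drop = FALSE],
                       ids = paste0("p", seq_len(ncol(pr))), loci = g$loci)
  y <- genotype_matrix(g$a1[pr[2, ], , drop = FALSE],
                       g$a2[pr[2, ], , drop = FALSE],
                       ids = paste0("q", seq_len(ncol(pr))), loci = g$loci)
  out <- data.frame(id1 = g$ids[pr[1, ]], id2 = g$ids[pr[2, ]],
                    stringsAsFactors = FALSE)
  for (est in estimators) {
    out[[est]] <- if (est == "DyadML") relatedness_dyadml(x, y, freqs)$r
                  else relatedness_moment(x, y, freqs, est)
  }
  out
}

#' Maximum-likelihood individual inbreeding coefficients
#'
#' Per individual, maximises over `f` in `[0, 1]` the multilocus
#' likelihood of its genotypes under partial self-identity:
#' `P(aa) = f p_a + (1-f) p_a^2`, `P(ab) = (1-f) 2 p_a p_b`. This is the
#' individual-level analogue of the dyadic likelihood machinery and is
#' reported without any endogamy threshold -- ranking, not labelling, is
#' the supported use.
#'
#' @param g a [genotype_matrix()].
#' @param freqs reference allele frequencies; default [allele_freqs()] of
#'   `g`.
#' @return A data.frame: `id`, `f` (ML estimate), `loglik`.
#' @export
individual_inbreeding <- function(g, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_freqs(g)
  freqs <- .check_freqs(freqs)
  n <- length(g$ids)
  f_hat <- ll <- numeric(n)
  for (i in seq_len(n)) {
    # per-locus likelihood columns for the two identity modes
    A_ibd <- A_hwe <- c()
    for (j in seq_along(g$loci)) {
      a <- g$a1[i, j]; b <- g$a2[i, j]
      if (is.na(a)) next
      p <- freqs[[j]]
      pa <- unname(p[as.character(a)]); pb <- unname(p[as.character(b)])
      A_ibd <- c(A_ibd, if (a == b) pa else 0)
      A_hwe <- c(A_hwe, if (a == b) pa^2 else 2 * pa * pb)
    }
    if (length(A_ibd) == 0L) { f_hat[i] <- NA; ll[i] <- NA; next }
    nll <- function(f) -sum(log(f * A_ibd + (1 - f) * A_hwe))
    opt <- stats::optimize(nll, c(0, 1), tol = 1e-8)
    f_hat[i] <- opt$minimum
    # snap interior optima created by the boundary tolerance
    if (nll(0) <= opt$objective) { f_hat[i] <- 0; opt$objective <- nll(0) }
    if (nll(1) <= opt$objective) { f_hat[i] <- 1; opt$objective <- nll(1) }
    ll[i] <- -opt$objective
  }
  data.frame(id = g$ids, f = f_hat, loglik = ll, stringsAsFactors = FALSE)
}
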