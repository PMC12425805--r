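# Variance-component heritability partitioning: genomic relatedness
# matrices for bQTL / matched-background / rest-of-genome SNP sets,
# matched sampling, multi-component average-information REML, MVN trait
# simulation and the permutation scheme.

#' Genomic relatedness (kinship) matrix from a genotype subset
#'
#' Centered cross-product `K = Z Z' / c` with `Z` the column-centered
#' genotype matrix and `c` chosen so that `mean(diag(K)) = 1`. Individuals
#' with identical genotypes get identical rows and columns.
#'
#' @param genotypes Individuals x markers numeric matrix (0/1 inbred
#'   coding or 0/1/2 dosages).
#' @return Symmetric individuals x individuals matrix.
#' @export
build_kinship <- function(genotypes) {
  if (is.null(dim(genotypes)) || ncol(genotypes) < 1L) {
    stop("need at least one marker", call. = FALSE)
  }
  Z <- scale(genotypes, center = TRUE, scale = FALSE)
  keep <- apply(Z, 2L, function(z) any(z != 0))
  if (!any(keep)) {
    stop("all markers have zero variance: no information", call. = FALSE)
  }
  Z <- Z[, keep, drop = FALSE]
  K <- tcrossprod(Z)
  K / mean(diag(K))
}

# distance-to-gene bins: intragenic, 0-1 kb, ..., 9-10 kb, >10 kb
.distance_bin <- function(d) {
  ifelse(d == 0, "intragenic",
         ifelse(d > 10000, ">10kb",
                paste0(pmin(floor((d - 1) / 1000), 9L), "-",
                       pmin(floor((d - 1) / 1000), 9L) + 1L, "kb")))
}

.af_bin <- function(af, width = 0.1) {
  b <- floor(af / width)
  b[af >= 1] <- ceiling(1 / width) - 1L   # AF of exactly 1 joins the top bin
  sprintf("[%.1f,%.1f)", b * width, (b + 1) * width)
}

#' Bin labels used for matched background sampling
#'
#' @param af Allele frequencies in `[0, 1]`.
#' @param dist_to_gene Distances to the nearest gene in bp (0 =
#'   intragenic).
#' @param af_bin_width Allele-frequency bin width (default 0.1).
#' @return Character vector of `AF-bin x distance-bin` cell labels.
#' @export
matching_cell <- function(af, dist_to_gene, af_bin_width = 0.1) {
  paste(.af_bin(af, af_bin_width), .distance_bin(dist_to_gene), sep = "|")
}

#' Sample a matched background SNP set
#'
#' Draws, for every bQTL SNP, one non-bQTL SNP without replacement from
#' the identical allele-frequency x distance-to-gene cell, so the bin-cell
#' histograms of the bQTL and background sets are exactly equal. When a
#' cell runs empty the nearest non-empty distance bin within the same AF
#' bin is used (with a warning).
#'
#' @param bqtl_ids Site ids of the bQTL SNPs.
#' @param all_sites data.frame with `site_id`, `af`, `dist_to_gene` for
#'   the whole marker panel.
#' @param af_bin_width Allele-frequency bin width (default 0.1).
#' @return Character vector of sampled background site ids (same length
#'   as `bqtl_ids`). Uses the current RNG stream.
#' @export
sample_matched_background <- function(bqtl_ids, all_sites,
                                      af_bin_width = 0.1) {
  pool <- all_sites[!all_sites$site_id %in% bqtl_ids, , drop = FALSE]
  pool_cell <- matching_cell(pool$af, pool$dist_to_gene, af_bin_width)
  bq <- all_sites[match(bqtl_ids, all_sites$site_id), , drop = FALSE]
  bq_cell <- matching_cell(bq$af, bq$dist_to_gene, af_bin_width)
  dist_order <- c("intragenic", paste0(0:9, "-", 1:10, "kb"), ">10kb")

  available <- split(seq_len(nrow(pool)), pool_cell)
  available <- lapply(available, function(i) i[sample.int(length(i))])
  taken <- setNames(integer(length(available)), names(available))
  out <- character(length(bqtl_ids))
  fallback <- FALSE
  for (i in seq_along(bqtl_ids)) {
    cell <- bq_cell[i]
    pick <- NA_integer_
    if (!is.null(available[[cell]]) &&
        taken[cell] < length(available[[cell]])) {
      taken[cell] <- taken[cell] + 1L
      pick <- available[[cell]][taken[cell]]
    } else {
      # nearest non-empty distance bin, same AF bin
      fallback <- TRUE
      parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
      di <- match(parts[2L], dist_order)
      for (off in order(abs(seq_along(dist_order) - di))[-1L]) {
        alt <- paste(parts[1L], dist_order[off], sep = "|")
        if (!is.null(available[[alt]]) &&
            taken[alt] < length(available[[alt]])) {
          taken[alt] <- taken[alt] + 1L
          pick <- available[[alt]][taken[alt]]
          break
        }
      }
      if (is.na(pick)) stop("background pool exhausted for AF bin ",
                            parts[1L], call. = FALSE)
    }
    out[i] <- pool$site_id[pick]
  }
  if (fallback) {
    warning("empty matching cell: nearest non-empty distance bin used")
  }
  out
}

# REML log-likelihood pieces for V = sum sigma2_k K_k + sigma2_e I and an
# intercept-only fixed effect. Returns P y, P, traces and the restricted
# log-likelihood.
.reml_pieces <- function(theta, Ks, y) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Ks)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  one <- rep(1, n)
  Vi1 <- Vi %*% one
  xvx <- sum(Vi1)                       # 1' V^-1 1
  P <- Vi - tcrossprod(Vi1) / xvx
  Py <- P %*% y
  ll <- -0.5 * (logdetV + log(xvx) + sum(y * Py))
  list(P = P, Py = Py, ll = ll)
}

#' Restricted log-likelihood of a variance-component model
#'
#' For `y = 1 mu + sum_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`,
#' `e ~ N(0, sigma2_e I)`. Exposed so independent optimizers can audit
#' [reml_fit()].
#'
#' @param theta Variance components `c(sigma2_1, ..., sigma2_K,
#'   sigma2_e)`.
#' @param kinships List of kinship matrices.
#' @param y Trait vector (no missing values).
#' @return The restricted log-likelihood (up to an additive constant), or
#'   `-Inf` if `V` is not positive definite.
#' @export
reml_loglik <- function(theta, kinships, y) {
  pc <- .reml_pieces(theta, kinships, y)
  if (is.null(pc)) return(-Inf)
  pc$ll
}

#' Multi-component REML fit (average information with EM fallback)
#'
#' Estimates the variance attributable to each kinship component plus an
#' i.i.d. residual by restricted maximum likelihood with an intercept-only
#' fixed effect. Updates use the average-information matrix; any step that
#' leaves the parameter space or decreases the restricted likelihood
#' falls back to an EM update. Components are constrained non-negative
#' (boundary at a small positive floor, zeroed on return).
#'
#' @param trait Numeric trait vector; individuals with missing values are
#'   dropped (with their kinship rows/columns).
#' @param kinships List of symmetric kinship matrices aligned to `trait`.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @param max_iter Maximum iterations (default 200).
#' @return Object of class `"varcomp"`: list with `variances` (named,
#'   residual last), `proportions`, `loglik`, `converged`, `iterations`,
#'   `n`.
#' @export
reml_fit <- function(trait, kinships, tol = 1e-6, max_iter = 200L) {
  if (!is.list(kinships)) kinships <- list(kinships)
  keep <- !is.na(trait)
  y <- trait[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 non-missing individuals", call. = FALSE)
  if (stats::var(y) == 0) stop("trait has zero variance", call. = FALSE)
  Ks <- lapply(kinships, function(K) K[keep, keep, drop = FALSE])
  nk <- length(Ks)
  vy <- stats::var(y)
  theta <- rep(vy / (nk + 1), nk + 1)
  floor_v <- vy * 1e-8

  pc <- .reml_pieces(theta, Ks, y)
  if (is.null(pc)) stop("initial V not positive definite", call. = FALSE)
  converged <- FALSE
  iter <- 0L
  Klist <- c(Ks, list(diag(1, n)))
  # active set: components pinned at the zero floor are dropped from the
  # AI update (the residual always stays active)
  active <- rep(TRUE, nk + 1L)
  pinned <- integer(nk + 1L)
  for (iter in seq_len(max_iter)) {
    P <- pc$P
    Py <- as.numeric(pc$Py)
    w <- lapply(Klist, function(K) K %*% Py)      # K_k P y
    score <- vapply(seq_along(Klist), function(k) {
      -0.5 * (sum(P * Klist[[k]]) - sum(Py * w[[k]]))
    }, numeric(1))
    act <- which(active)
    AI <- matrix(0, length(act), length(act))
    Pw <- lapply(w[act], function(wk) P %*% wk)
    for (i in seq_along(act)) {
      for (j in i:length(act)) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[act[i]]] * Pw[[j]])
      }
    }
    step_act <- tryCatch(solve(AI, score[act]), error = function(e) NULL)
    new_pc <- NULL
    if (!is.null(step_act)) {
      # step-halve the AI update until the restricted likelihood ascends
      for (s in 0.5^(0:6)) {
        cand <- theta
        cand[act] <- pmax(theta[act] + s * step_act, floor_v)
        try_pc <- .reml_pieces(cand, Ks, y)
        if (!is.null(try_pc) && try_pc$ll >= pc$ll - 1e-10) {
          new_pc <- try_pc
          break
        }
      }
    }
    if (is.null(new_pc)) {
      # EM fallback: guaranteed ascent, slow but safe
      cand <- theta
      cand[act] <- vapply(act, function(k) {
        (theta[k]^2 * sum(Py * w[[k]]) +
           theta[k] * (n - theta[k] * sum(P * Klist[[k]]))) / n
      }, numeric(1))
      cand[act] <- pmax(cand[act], floor_v)
      new_pc <- .reml_pieces(cand, Ks, y)
      if (is.null(new_pc)) break
    }
    # pin components that keep landing on the floor with a non-positive
    # score (the likelihood does not improve by raising them)
    hit <- active & cand <= floor_v * 1.01 & score <= 0
    hit[nk + 1L] <- FALSE
    pinned[hit] <- pinned[hit] + 1L
    pinned[!hit] <- 0L
    active[pinned >= 2L] <- FALSE
    done <- abs(new_pc$ll - pc$ll) < tol * (abs(pc$ll) + 1)
    theta <- cand
    pc <- new_pc
    if (done) { converged <- TRUE; break }
  }
  theta[theta <= floor_v * 1.01] <- 0
  names(theta) <- c(
    if (!is.null(names(kinships)) && all(nzchar(names(kinships)))) {
      names(kinships)
    } else paste0("K", seq_len(nk)),
    "residual"
  )
  structure(
    list(variances = theta, proportions = theta / sum(theta),
         loglik = pc$ll, converged = converged, iterations = iter, n = n),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("REML variance components (n = %d, %s after %d iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(rbind(variance = x$variances,
                    proportion = x$proportions), 4))
  invisible(x)
}

# eigendecomposition with smallest-eigenvalue clipping for MVN sampling
.psd_root <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values)))) {
    warning("kinship not PSD: negative eigenvalues clipped to zero")
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate traits from kinship covariances
#'
#' Each trait is the sum of independent multivariate normal draws, one per
#' kinship component with covariance `h2_k * K_k` plus a residual
#' `N(0, h2_e * I)`; heritabilities must sum to 1 so traits have unit
#' expected variance.
#'
#' @param kinships List of kinship matrices.
#' @param h2 Heritability vector: one entry per kinship plus the residual,
#'   non-negative; a shortfall from 1 is added to the residual.
#' @param n_traits Number of traits to draw.
#' @return Individuals x traits matrix. Uses the current RNG stream.
#' @export
simulate_traits <- function(kinships, h2, n_traits = 10L) {
  if (!is.list(kinships)) kinships <- list(kinships)
  nk <- length(kinships)
  if (length(h2) == nk) h2 <- c(h2, 0)
  if (length(h2) != nk + 1L) {
    stop("`h2` needs one entry per kinship plus the residual", call. = FALSE)
  }
  if (any(h2 < 0)) stop("heritabilities must be >= 0", call. = FALSE)
  if (sum(h2) > 1 + 1e-8) stop("heritabilities must sum to <= 1",
                               call. = FALSE)
  h2[nk + 1L] <- h2[nk + 1L] + (1 - sum(h2))
  n <- nrow(kinships[[1L]])
  roots <- lapply(kinships, .psd_root)
  Y <- matrix(0, n, n_traits)
  for (k in seq_len(nk)) {
    if (h2[k] > 0) {
      Y <- Y + sqrt(h2[k]) * roots[[k]] %*%
        matrix(stats::rnorm(n * n_traits), n, n_traits)
    }
  }
  Y + sqrt(h2[nk + 1L]) * matrix(stats::rnorm(n * n_traits), n, n_traits)
}

#' Recovery experiment for the REML pipeline
#'
#' The validation design of the study: for each heritability set, simulate
#' traits from the kinship covariances, re-estimate the components with
#' [reml_fit()] and report estimated against true proportions.
#'
#' @param kinships List of kinship matrices.
#' @param h2_sets List of heritability vectors (per kinship + residual).
#' @param n_traits_per_set Traits per set (default 10).
#' @param tol REML tolerance.
#' @return data.frame with one row per set x component: `set`,
#'   `component`, `truth`, `mean_estimate`, `sd_estimate`, `bias`.
#' @export
recovery_experiment <- function(kinships, h2_sets, n_traits_per_set = 10L,
                                tol = 1e-6) {
  nk <- length(kinships)
  comp_names <- c(paste0("K", seq_len(nk)), "residual")
  rows <- list()
  for (s in seq_along(h2_sets)) {
    h2 <- h2_sets[[s]]
    if (length(h2) == nk) h2 <- c(h2, 1 - sum(h2))
    Y <- simulate_traits(kinships, h2, n_traits_per_set)
    est <- t(apply(Y, 2L, function(y) {
      reml_fit(y, kinships, tol = tol)$proportions
    }))
    for (k in seq_len(nk + 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        set = s, component = comp_names[k], truth = h2[k],
        mean_estimate = mean(est[, k]), sd_estimate = stats::sd(est[, k]),
        bias = mean(est[, k]) - h2[k], stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation scheme over matched background sets
#'
#' Repeats the partitioning `n_perm` times: the bQTL SNP set (and its
#' kinship) is held fixed while the matched background set is resampled,
#' the background and rest-of-genome kinships rebuilt, and every trait
#' refitted, yielding a distribution of variance-proportion estimates per
#' trait and component.
#'
#' @param bqtl_ids bQTL site ids (fixed across permutations).
#' @param all_sites Site table with `site_id`, `af`, `dist_to_gene`.
#' @param genotypes Individuals x markers matrix (columns named by site
#'   id) for the mapping population.
#' @param traits Individuals x traits matrix.
#' @param n_perm Number of permutations (default 100).
#' @param tol REML tolerance.
#' @return data.frame with one row per permutation x trait x component:
#'   `perm`, `trait`, `component`, `proportion`. The bQTL kinship is
#'   attached as attribute `"K_bqtl"`.
#' @export
vcap_permutations <- function(bqtl_ids, all_sites, genotypes, traits,
                              n_perm = 100L, tol = 1e-6) {
  traits <- as.matrix(traits)
  if (is.null(colnames(traits))) {
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  }
  K_bqtl <- build_kinship(genotypes[, bqtl_ids, drop = FALSE])
  rows <- vector("list", n_perm * ncol(traits))
  ri <- 0L
  for (p in seq_len(n_perm)) {
    bg_ids <- sample_matched_background(bqtl_ids, all_sites)
    rest_ids <- setdiff(colnames(genotypes), c(bqtl_ids, bg_ids))
    Ks <- list(
      bqtl = K_bqtl,
      bg = build_kinship(genotypes[, bg_ids, drop = FALSE]),
      rest = build_kinship(genotypes[, rest_ids, drop = FALSE])
    )
    for (tr in seq_len(ncol(traits))) {
      fit <- reml_fit(traits[, tr], Ks, tol = tol)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        perm = p, trait = colnames(traits)[tr],
        component = names(fit$proportions),
        proportion = unname(fit$proportions),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "K_bqtl") <- K_bqtl
  out
}
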