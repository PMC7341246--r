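#' Variance components of an animal model
#'
#' Container for the (co)variances of the random terms: additive direct
#' (`sigma2_a`), additive maternal (`sigma2_m`), their covariance
#' (`sigma_am`), permanent environment (`sigma2_p`) and residual
#' (`sigma2_e`). Derived ratios use the phenotypic variance
#' `sigma2_P = sigma2_a + sigma2_m + sigma_am + sigma2_p + sigma2_e`.
#'
#' @param sigma2_a,sigma2_e Direct genetic and residual variances (>= 0,
#'   residual > 0).
#' @param sigma2_m,sigma_am,sigma2_p Maternal variance, direct-maternal
#'   covariance and permanent-environment variance.
#' @return List of class `variance_components` with derived `h2`, `m2`,
#'   `r_am`, `c2`.
#' @export
variance_components <- function(sigma2_a, sigma2_e, sigma2_m = 0,
                                sigma_am = 0, sigma2_p = 0) {
  if (any(c(sigma2_a, sigma2_m, sigma2_p) < 0) || sigma2_e <= 0) {
    stop("variances must be >= 0 and sigma2_e > 0", call. = FALSE)
  }
  if (sigma2_m > 0) {
    r_am <- sigma_am / sqrt(sigma2_a * sigma2_m)
    if (abs(r_am) > 1 + 1e-12) {
      stop("|r_AM| must be <= 1 (genetic block not PSD)", call. = FALSE)
    }
  } else {
    if (sigma_am != 0) stop("sigma_am requires sigma2_m > 0", call. = FALSE)
    r_am <- NA_real_
  }
  sp <- sigma2_a + sigma2_m + sigma_am + sigma2_p + sigma2_e
  structure(
    list(sigma2_a = sigma2_a, sigma2_m = sigma2_m, sigma_am = sigma_am,
         sigma2_p = sigma2_p, sigma2_e = sigma2_e, sigma2_P = sp,
         h2 = sigma2_a / sp, m2 = sigma2_m / sp, r_am = r_am,
         c2 = sigma2_p / sp),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> h2 =", signif(x$h2, 4),
      if (x$sigma2_m > 0) paste("m2 =", signif(x$m2, 4),
                                "r_AM =", signif(x$r_am, 4)) else "",
      if (x$sigma2_p > 0) paste("c2 =", signif(x$c2, 4)) else "", "\n")
  invisible(x)
}

#' Animal-model specification
#'
#' Which terms enter the linear mixed model for a trait: a fixed-effect
#' formula (evaluated against the phenotype table), the additive direct
#' effect (always present), and optionally a maternal genetic effect and a
#' permanent-environment effect. The permanent-environment term attaches to
#' the animal itself (repeated own records) or to the dam (maternally
#' influenced calf traits).
#'
#' @param trait Name of the phenotype column in the records.
#' @param fixed One-sided formula of fixed effects (default `~ 1`).
#' @param maternal Fit an additive maternal genetic effect (requires a
#'   `dam` column in the records)?
#' @param permanent `"none"`, `"animal"` or `"dam"`.
#' @param covariance_am Fit the direct-maternal genetic covariance?
#' @return List of class `model_spec`.
#' @export
model_spec <- function(trait, fixed = ~1, maternal = FALSE,
                       permanent = c("none", "animal", "dam"),
                       covariance_am = maternal) {
  permanent <- match.arg(permanent)
  if (covariance_am && !maternal) {
    stop("covariance_am requires a maternal term", call. = FALSE)
  }
  structure(list(trait = trait, fixed = fixed, maternal = maternal,
                 permanent = permanent, covariance_am = covariance_am),
            class = "model_spec")
}

# records -> incidence matrix onto `levels`
.incidence <- function(ids, levels) {
  m <- matrix(0, length(ids), length(levels))
  m[cbind(seq_along(ids), match(ids, levels))] <- 1
  m
}

#' Solve the mixed-model equations of an animal model
#'
#' Henderson's MME with the A-inverse-scaled genetic block (a 2x2
#' direct-maternal kronecker block when a maternal term with covariance is
#' fitted) and an identity block for the permanent-environment term.
#' Prediction error variances come from the diagonal of the inverse
#' coefficient matrix; reliability is `1 - PEV / sigma2_a`.
#'
#' @param records Phenotype tibble: column `animal`, the trait column named
#'   in `model`, a `dam` column when a maternal/dam term is fitted, plus any
#'   fixed-effect covariates.
#' @param ped Pedigree tibble covering every record's animal (and dam when
#'   maternal effects are fitted).
#' @param vc A [variance_components()] object.
#' @param model A [model_spec()].
#' @return Object of class `animal_model_fit`: tibbles `fixed` (term,
#'   estimate), `ebv` (animal, ebv, pev, reliability; every pedigree
#'   animal), plus `maternal` and `permanent` solutions when fitted.
#'   [tidy()][generics::tidy] returns the EBV table, `glance()` the model
#'   dimensions.
#' @export
solve_mme <- function(records, ped, vc, model = model_spec("value")) {
  records <- tibble::as_tibble(records)
  if (!model$trait %in% names(records)) {
    stop("records lack trait column `", model$trait, "`", call. = FALSE)
  }
  ainv_obj <- pedigree_ainverse(ped)
  animals <- ainv_obj$animals
  if (!all(records$animal %in% animals)) {
    stop("records contain animals absent from the pedigree", call. = FALSE)
  }
  y <- records[[model$trait]]
  n <- length(y)
  q <- length(animals)
  X <- stats::model.matrix(model$fixed, records)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effects design is rank deficient; confounded columns: ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "),
         call. = FALSE)
  }
  Za <- .incidence(records$animal, animals)
  ainv <- as.matrix(ainv_obj$ainv)

  blocks <- list(X, Za)
  use_m <- isTRUE(model$maternal)
  use_p <- model$permanent != "none"
  if (use_m || model$permanent == "dam") {
    if (is.null(records$dam)) {
      stop("maternal/dam terms need a `dam` column in records", call. = FALSE)
    }
    if (!all(records$dam %in% animals)) {
      stop("record dams absent from the pedigree", call. = FALSE)
    }
  }
  if (use_m) blocks <- c(blocks, list(.incidence(records$dam, animals)))
  pe_levels <- NULL
  if (use_p) {
    pe_ids <- if (model$permanent == "animal") records$animal else records$dam
    pe_levels <- unique(pe_ids)
    blocks <- c(blocks, list(.incidence(pe_ids, pe_levels)))
  }
  W <- do.call(cbind, blocks)
  C <- crossprod(W)
  rhs <- crossprod(W, y)

  p <- ncol(X)
  ia <- p + seq_len(q)
  off <- p + q
  if (use_m) {
    g0 <- matrix(c(vc$sigma2_a, vc$sigma_am, vc$sigma_am, vc$sigma2_m), 2)
    if (!model$covariance_am) g0[1, 2] <- g0[2, 1] <- 0
    k <- solve(g0) * vc$sigma2_e
    im <- off + seq_len(q)
    C[ia, ia] <- C[ia, ia] + ainv * k[1, 1]
    C[im, im] <- C[im, im] + ainv * k[2, 2]
    C[ia, im] <- C[ia, im] + ainv * k[1, 2]
    C[im, ia] <- C[im, ia] + ainv * k[2, 1]
    off <- off + q
  } else {
    C[ia, ia] <- C[ia, ia] + ainv * (vc$sigma2_e / vc$sigma2_a)
  }
  if (use_p) {
    ip <- off + seq_len(length(pe_levels))
    C[ip, ip] <- C[ip, ip] + diag(length(pe_levels)) *
      (vc$sigma2_e / vc$sigma2_p)
  }
  cinv <- solve(C)
  sol <- unname(drop(cinv %*% rhs))
  pev <- unname(diag(cinv)[ia]) * vc$sigma2_e
  rel <- pmin(pmax(1 - pev / vc$sigma2_a, 0), 1)
  out <- list(
    fixed = tibble::tibble(term = colnames(X), estimate = sol[seq_len(p)]),
    ebv = tibble::tibble(animal = animals, ebv = sol[ia], pev = pev,
                         reliability = rel),
    vc = vc, model = model, n_records = n, n_animals = q
  )
  if (use_m) {
    out$maternal <- tibble::tibble(animal = animals, mbv = sol[p + q + seq_len(q)])
  }
  if (use_p) {
    ip <- (ncol(C) - length(pe_levels) + 1):ncol(C)
    out$permanent <- tibble::tibble(id = pe_levels, pe = sol[ip])
  }
  class(out) <- "animal_model_fit"
  out
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat("<animal_model_fit> trait:", x$model$trait, "-", x$n_records,
      "records,", x$n_animals, "animals\n")
  print(x$fixed)
  invisible(x)
}

#' @rdname solve_mme
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @method tidy animal_model_fit
#' @export
tidy.animal_model_fit <- function(x, ...) x$ebv

#' @rdname solve_mme
#' @method glance animal_model_fit
#' @export
glance.animal_model_fit <- function(x, ...) {
  tibble::tibble(trait = x$model$trait, n_records = x$n_records,
                 n_animals = x$n_animals, h2 = x$vc$h2,
                 maternal = isTRUE(x$model$maternal),
                 permanent = x$model$permanent)
}

#' EM-REML for the direct-effects animal model
#'
#' Estimates `sigma2_a` and `sigma2_e` of the model
#' `y = Xb + Z a + e`, `a ~ N(0, A sigma2_a)`, by expectation-maximisation
#' on Henderson's MME: each iteration solves the MME at the current
#' variances and updates `sigma2_a` from `a' A^-1 a` plus the trace of
#' `A^-1` against the a-block of the inverse coefficient matrix, and
#' `sigma2_e` from the residual quadratic form. The REML log-likelihood is
#' non-decreasing across iterations.
#'
#' @param records Phenotype tibble with `animal`, the trait column, and any
#'   fixed covariates.
#' @param ped Pedigree tibble.
#' @param init Starting [variance_components()] (only `sigma2_a`,
#'   `sigma2_e` used); default splits the phenotypic variance equally.
#' @param fixed Fixed-effect formula (default `~ 1`).
#' @param trait Trait column name (default `"value"`).
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @param keep_loglik Record the REML log-likelihood at each iterate?
#' @return Object of class `reml_fit`: the estimated
#'   [variance_components()], `h2`, iteration count, convergence flag and
#'   (optionally) the log-likelihood trace.
#' @export
em_reml_direct <- function(records, ped, init = NULL, fixed = ~1,
                           trait = "value", tol = 1e-8, max_iter = 500L,
                           keep_loglik = FALSE) {
  records <- tibble::as_tibble(records)
  y <- records[[trait]]
  if (is.null(y)) stop("records lack trait column `", trait, "`", call. = FALSE)
  ainv_obj <- pedigree_ainverse(ped)
  animals <- ainv_obj$animals
  if (!all(records$animal %in% animals)) {
    stop("records contain animals absent from the pedigree", call. = FALSE)
  }
  ainv <- as.matrix(ainv_obj$ainv)
  X <- stats::model.matrix(fixed, records)
  Za <- .incidence(records$animal, animals)
  n <- length(y)
  p <- qr(X)$rank
  q <- length(animals)
  if (is.null(init)) {
    v0 <- stats::var(y)
    init <- variance_components(sigma2_a = v0 / 2, sigma2_e = v0 / 2)
  }
  s2a <- init$sigma2_a
  s2e <- init$sigma2_e
  if (s2a <= 0) s2a <- stats::var(y) / 10
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Za)
  ZtZ <- crossprod(Za)
  Xty <- crossprod(X, y)
  Zty <- crossprod(Za, y)
  yty <- sum(y^2)
  A <- NULL
  if (keep_loglik) A <- solve(ainv)
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    alpha <- s2e / s2a
    C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + ainv * alpha))
    cinv <- solve(C)
    sol <- cinv %*% rbind(Xty, Zty)
    ahat <- sol[ncol(X) + seq_len(q), 1L]
    caa <- cinv[ncol(X) + seq_len(q), ncol(X) + seq_len(q)]
    s2a_new <- (drop(crossprod(ahat, ainv %*% ahat)) +
                  sum(ainv * caa) * s2e) / q
    s2e_new <- drop(yty - crossprod(sol[seq_len(ncol(X)), 1L], Xty) -
                      crossprod(ahat, Zty)) / (n - p)
    if (keep_loglik) {
      V <- Za %*% A %*% t(Za) * s2a_new + diag(n) * s2e_new
      ch <- chol(V)
      vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
      vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
      xtvx <- crossprod(X, vinv_X)
      beta <- solve(xtvx, crossprod(X, vinv_y))
      py <- vinv_y - vinv_X %*% beta
      loglik <- c(loglik,
                  -0.5 * (2 * sum(log(diag(ch))) +
                            determinant(xtvx)$modulus[1] +
                            drop(crossprod(y, py))))
    }
    rel <- max(abs(s2a_new - s2a), abs(s2e_new - s2e)) /
      max(s2a, s2e, .Machine$double.eps)
    s2a <- max(s2a_new, .Machine$double.eps)
    s2e <- s2e_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  vc <- variance_components(sigma2_a = s2a, sigma2_e = s2e)
  structure(list(vc = vc, h2 = vc$h2, iterations = it, converged = converged,
                 loglik = if (keep_loglik) loglik else NULL),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> h2 =", signif(x$h2, 4), "in", x$iterations, "iterations",
      if (!x$converged) "(NOT converged)" else "", "\n")
  invisible(x)
}

#' @rdname em_reml_direct
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(component = c("sigma2_a", "sigma2_e"),
                 estimate = c(x$vc$sigma2_a, x$vc$sigma2_e))
}

#' @rdname em_reml_direct
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, iterations = x$iterations,
                 converged = x$converged)
}

#' Deregress estimated breeding values
#'
#' Simplified Garrick-style deregression without parent-average removal,
#' suited to shallow pedigrees: `DEBV = EBV / r2` and the association
#' weight is `w = (1 - c) / (c + (1 - r2) / r2)`, where `r2` is the EBV
#' reliability and `c` the fraction of genetic variance not explained by
#' markers. Animals with reliability below `r2_floor` (or exactly 0, where
#' the quotient is undefined) are excluded with a warning.
#'
#' @param ebv Tibble with columns `animal`, `ebv`, `reliability`.
#' @param c Fraction of genetic variance not captured by markers
#'   (default 0.10).
#' @param r2_floor Minimum reliability processed (default 0.05).
#' @return Tibble with `animal`, `ebv`, `reliability`, `debv`, `w`.
#' @export
#' @examples
#' deregress_ebv(tibble::tibble(animal = "a", ebv = 2, reliability = 0.5))
deregress_ebv <- function(ebv, c = 0.10, r2_floor = 0.05) {
  stopifnot(c > 0, c < 1)
  ebv <- tibble::as_tibble(ebv)
  r2 <- ebv$reliability
  if (any(r2 < 0 | r2 > 1)) stop("reliability outside [0,1]", call. = FALSE)
  drop <- r2 < r2_floor | r2 == 0
  if (any(drop)) {
    warning(sum(drop), " animal(s) excluded: reliability below ", r2_floor,
            call. = FALSE)
  }
  out <- ebv[!drop, ]
  out$debv <- out$ebv / out$reliability
  out$w <- (1 - c) / (c + (1 - out$reliability) / out$reliability)
  out
}
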