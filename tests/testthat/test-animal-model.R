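test_that("pedigree validation orders parents first and names cycles", {
  ped <- tibble::tibble(animal = c("c", "a", "b"),
                        sire = c("a", NA, NA), dam = c("b", NA, NA))
  pt <- pedigree_table(ped)
  expect_equal(pt$animal[3], "c")
  cyc <- tibble::tibble(animal = c("x", "y"), sire = c("y", "x"),
                        dam = c(NA, NA))
  expect_error(pedigree_table(cyc), "cycle")
  # parents appearing only as parents become founders
  ped2 <- tibble::tibble(animal = "k", sire = "s", dam = "d")
  expect_equal(nrow(pedigree_table(ped2)), 3L)
})

test_that("textbook inbreeding identities hold", {
  founders <- tibble::tibble(animal = c("a", "b"), sire = NA_character_,
                             dam = NA_character_)
  expect_true(all(pedigree_inbreeding(founders)$f == 0))
  # offspring of full sibs from unrelated grandparents: F = 0.25
  ped <- tibble::tibble(
    animal = c("gs", "gd", "s", "d", "x"),
    sire = c(NA, NA, "gs", "gs", "s"),
    dam = c(NA, NA, "gd", "gd", "d")
  )
  fi <- pedigree_inbreeding(ped)
  expect_equal(fi$f[fi$animal == "x"], 0.25)
  # parent-offspring mating: F = 0.25 as well
  ped2 <- tibble::tibble(animal = c("p", "q", "r"),
                         sire = c(NA, "p", "p"), dam = c(NA, NA, "q"))
  expect_equal(pedigree_inbreeding(ped2)$f[3], 0.25)
})

test_that("A-inverse equals the dense inverse of the tabular A", {
  founders <- tibble::tibble(animal = letters[1:4], sire = NA_character_,
                             dam = NA_character_)
  expect_equal(as.matrix(pedigree_ainverse(founders)$ainv),
               diag(4), ignore_attr = TRUE)
  # 8-animal pedigree with an inbred loop
  ped8 <- tibble::tibble(
    animal = sprintf("a%d", 1:8),
    sire = c(NA, NA, NA, "a1", "a1", "a4", "a4", "a6"),
    dam = c(NA, NA, NA, "a2", "a3", "a5", "a5", "a7")
  )
  A <- tabular_a(ped8)
  expect_equal(as.matrix(pedigree_ainverse(ped8)$ainv), solve(A),
               tolerance = 1e-10, ignore_attr = TRUE)
  # inbreeding agrees with the tabular diagonal
  expect_equal(pedigree_inbreeding(ped8)$f, unname(diag(A)) - 1,
               tolerance = 1e-12)
  # 50-animal random pedigree
  ped50 <- random_pedigree(50, seed = 3)
  A50 <- tabular_a(ped50)
  expect_equal(as.matrix(pedigree_ainverse(ped50)$ainv), solve(A50),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pedigree_inbreeding(ped50)$f, unname(diag(A50)) - 1,
               tolerance = 1e-12)
})

gls_oracle <- function(records, ped, vc, Zm_cov = NULL) {
  A <- tabular_a(ped)
  animals <- colnames(A)
  n <- nrow(records)
  Za <- matrix(0, n, length(animals))
  Za[cbind(seq_len(n), match(records$animal, animals))] <- 1
  V <- Za %*% A %*% t(Za) * vc$sigma2_a + diag(n) * vc$sigma2_e
  if (!is.null(Zm_cov)) {
    Zm <- Zm_cov
    V <- V + Zm %*% A %*% t(Zm) * vc$sigma2_m +
      (Za %*% A %*% t(Zm) + Zm %*% A %*% t(Za)) * vc$sigma_am
  }
  X <- matrix(1, n, 1)
  vinv <- solve(V)
  b <- solve(t(X) %*% vinv %*% X, t(X) %*% vinv %*% records$value)
  resid <- records$value - X %*% b
  cov_a <- A %*% t(Za) * vc$sigma2_a
  if (!is.null(Zm_cov)) cov_a <- cov_a + A %*% t(Zm_cov) * vc$sigma_am
  a <- cov_a %*% vinv %*% resid
  out <- list(b = unname(drop(b)), a = unname(drop(a)), animals = animals)
  if (!is.null(Zm_cov)) {
    cov_m <- A %*% t(Zm_cov) * vc$sigma2_m + A %*% t(Za) * vc$sigma_am
    out$m <- unname(drop(cov_m %*% vinv %*% resid))
  }
  out
}

test_that("MME solutions equal the GLS oracle on a direct-effects toy", {
  set.seed(51)
  ped <- tibble::tibble(
    animal = sprintf("a%d", 1:8),
    sire = c(NA, NA, NA, "a1", "a1", "a4", "a4", "a6"),
    dam = c(NA, NA, NA, "a2", "a3", "a5", "a5", "a7")
  )
  rec <- tibble::tibble(animal = sprintf("a%d", 4:8),
                        value = stats::rnorm(5, 10, 2))
  vc <- variance_components(sigma2_a = 2, sigma2_e = 3)
  fit <- solve_mme(rec, ped, vc)
  orc <- gls_oracle(rec, ped, vc)
  expect_equal(fit$fixed$estimate, orc$b, tolerance = 1e-8)
  expect_equal(fit$ebv$ebv, orc$a, tolerance = 1e-8)
  expect_true(all(fit$ebv$pev >= 0))
  expect_true(all(fit$ebv$reliability >= 0 & fit$ebv$reliability <= 1))
  expect_equal(tidy(fit), fit$ebv)
})

test_that("vanishing genetic variance shrinks EBVs to zero and b to OLS", {
  set.seed(52)
  ped <- random_pedigree(12, seed = 4)
  rec <- tibble::tibble(animal = ped$animal[5:12],
                        value = stats::rnorm(8, 5))
  vc <- variance_components(sigma2_a = 1e-10, sigma2_e = 1)
  fit <- solve_mme(rec, ped, vc)
  expect_lt(max(abs(fit$ebv$ebv)), 1e-6)
  expect_equal(fit$fixed$estimate, mean(rec$value), tolerance = 1e-6)
})

test_that("direct-maternal model with negative covariance matches a dense solve", {
  set.seed(53)
  ped <- tibble::tibble(
    animal = c("d1", "d2", "s1", "x1", "x2", "x3", "x4"),
    sire = c(NA, NA, NA, "s1", "s1", "s1", "s1"),
    dam = c(NA, NA, NA, "d1", "d1", "d2", "d2")
  )
  rec <- tibble::tibble(animal = c("x1", "x2", "x3", "x4"),
                        dam = c("d1", "d1", "d2", "d2"),
                        value = stats::rnorm(4, 20, 3))
  vc <- variance_components(sigma2_a = 2, sigma2_e = 4, sigma2_m = 1,
                            sigma_am = -0.5)
  fit <- solve_mme(rec, ped, vc,
                   model_spec("value", maternal = TRUE,
                              covariance_am = TRUE))
  A <- tabular_a(ped)
  animals <- colnames(A)
  Zm <- matrix(0, 4, length(animals))
  Zm[cbind(1:4, match(rec$dam, animals))] <- 1
  orc <- gls_oracle(rec, ped, vc, Zm_cov = Zm)
  expect_equal(fit$fixed$estimate, orc$b, tolerance = 1e-8)
  expect_equal(fit$ebv$ebv, orc$a, tolerance = 1e-8)
  expect_equal(fit$maternal$mbv, orc$m, tolerance = 1e-8)
})

test_that("rank-deficient fixed effects raise a named error", {
  ped <- random_pedigree(8, seed = 5)
  rec <- tibble::tibble(animal = ped$animal[3:8],
                        value = stats::rnorm(6),
                        x1 = c(1, 2, 3, 4, 5, 6))
  rec$x2 <- 2 * rec$x1  # collinear covariate
  expect_error(
    solve_mme(rec, ped, variance_components(1, 1),
              model_spec("value", fixed = ~ x1 + x2)),
    "rank deficient"
  )
})

test_that("EM-REML is scale-equivariant with non-decreasing likelihood", {
  cfg <- sim_config(seed = 55, n_founders = 30, n_generations = 2,
                    n_per_generation = 60,
                    trait = list(var_p = 4, h2 = 0.4))
  ped <- sim_pedigree(cfg)
  sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = FALSE)
  r1 <- em_reml_direct(sim$records, ped, keep_loglik = TRUE)
  expect_true(all(diff(r1$loglik) > -1e-6))
  rec2 <- sim$records
  rec2$value <- rec2$value * 2
  r2 <- em_reml_direct(rec2, ped)
  expect_equal(r2$vc$sigma2_a, 4 * r1$vc$sigma2_a, tolerance = 1e-4)
  expect_equal(r2$vc$sigma2_e, 4 * r1$vc$sigma2_e, tolerance = 1e-4)
  expect_equal(r2$h2, r1$h2, tolerance = 1e-5)
  expect_s3_class(glance(r1), "tbl_df")
})

test_that("EM-REML finds little genetic variance in a null simulation", {
  cfg <- sim_config(seed = 56, n_founders = 40, n_generations = 2,
                    n_per_generation = 100,
                    trait = list(var_p = 1, h2 = 0))
  ped <- sim_pedigree(cfg)
  sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = FALSE,
                                record_animals = ped$animal[ped$generation > 0])
  r <- em_reml_direct(sim$records, ped)
  expect_lt(r$h2, 0.1)
})

test_that("deregression follows the contracted arithmetic", {
  # reliability 1: identity with weight (1-c)/c
  d1 <- deregress_ebv(tibble::tibble(animal = "a", ebv = 3.2,
                                     reliability = 1), c = 0.10)
  expect_equal(d1$debv, 3.2)
  expect_equal(d1$w, 9)
  # hand-worked case
  d2 <- deregress_ebv(tibble::tibble(animal = "b", ebv = 2,
                                     reliability = 0.5), c = 0.10)
  expect_equal(d2$debv, 4, tolerance = 1e-12)
  expect_equal(d2$w, 0.9 / 1.1, tolerance = 1e-12)
  # monotonicity over a reliability grid at fixed EBV > 0
  r2 <- seq(0.05, 1, by = 0.05)
  dd <- deregress_ebv(tibble::tibble(animal = sprintf("m%02d", seq_along(r2)),
                                     ebv = 2, reliability = r2))
  expect_true(all(diff(dd$debv) <= 0))
  expect_true(all(diff(dd$w) > 0))
  # exclusions below the floor
  expect_warning(
    d3 <- deregress_ebv(tibble::tibble(animal = c("x", "y"), ebv = c(1, 1),
                                       reliability = c(0.01, 0.5))),
    "excluded"
  )
  expect_equal(d3$animal, "y")
})

test_that("deregression de-shrinks towards true breeding values", {
  # BLUP shrinkage: the regression of EBV on TBV has slope ~ r2 < 1, while
  # deregressed EBVs behave like unshrunken pseudo-records with slope ~ 1
  set.seed(57)
  n <- 600
  tbv <- stats::rnorm(n)
  r2 <- stats::runif(n, 0.25, 0.45)
  ebv <- r2 * tbv + stats::rnorm(n, 0, sqrt(r2 * (1 - r2)))
  d <- deregress_ebv(tibble::tibble(animal = as.character(1:n), ebv = ebv,
                                    reliability = r2))
  slope_ebv <- stats::coef(stats::lm(ebv ~ tbv))[2]
  slope_debv <- stats::coef(stats::lm(d$debv ~ tbv))[2]
  expect_lt(slope_ebv, 0.6)                  # shrunken towards mean r2
  expect_equal(unname(slope_debv), 1, tolerance = 0.15)
})
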