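test_that("nearest-prototype classification reproduces the published winners", {
  ex <- pf_example("patterns")
  r <- pf_classify(ex$prototypes, ex$query, "hamming", context = "table3")
  expect_equal(glance(r)$best, "P2")
  expect_within(tidy(r)$distance[order(tidy(r)$alternative)],
                c(1.1, 0.3, 1.4)[order(c("P1", "P2", "P3"))], 5e-5)
  expect_false(glance(r)$is_tie)

  dg <- pf_example("diagnoses")
  r4 <- pf_classify(dg$prototypes, dg$query, "hamming", context = "table4")
  expect_equal(glance(r4)$best, "P1 (Malaria)")
  expect_within(glance(r4)$best_distance, 0.8, 5e-5)
})

test_that("a query identical to a prototype wins with distance zero", {
  ex <- pf_example("patterns")
  protos <- proto_sets(ex$prototypes)
  r <- pf_classify(ex$prototypes, protos$P3, "euclidean", context = "table3")
  expect_equal(glance(r)$best, "P3")
  expect_equal(glance(r)$best_distance, 0)
})

test_that("classification is invariant under prototype relabelling", {
  ex <- pf_example("patterns")
  shuffled <- ex$prototypes[order(match(ex$prototypes$prototype,
                                        c("P3", "P1", "P2"))), ]
  r1 <- pf_classify(ex$prototypes, ex$query, "chordal", p = 2)
  r2 <- pf_classify(shuffled, ex$query, "chordal", p = 2)
  expect_equal(glance(r1)$best, glance(r2)$best)
  expect_equal(dplyr::arrange(tidy(r1), alternative),
               dplyr::arrange(tidy(r2), alternative))
})

test_that("exact ties are flagged and broken towards the earlier prototype", {
  A <- pfset(c(0.5, 0.2), c(0.3, 0.6))
  protos <- list(first = A, second = A)
  r <- pf_classify(protos, pfset(c(0.4, 0.1), c(0.4, 0.7)), "hamming")
  expect_true(glance(r)$is_tie)
  expect_equal(glance(r)$best, "first")
})

test_that("the ideal medicine is the polarity-oriented column extremum", {
  med <- pf_example("medicines")
  ideal <- pf_ideal(med)
  expect_equal(ideal$mu, c(0.1, 0.1, 0.1, 0.1, 0.1, 0.9, 0.8, 0.8))
  expect_equal(ideal$nu, c(0.9, 0.9, 0.9, 0.8, 0.8, 0.2, 0.3, 0.4))
  # single alternative: the ideal is that row
  one <- pf_decision_matrix(
    tibble::tibble(alternative = "A", criterion = c("c1", "c2"),
                   mu = c(0.3, 0.6), nu = c(0.5, 0.2)),
    polarity = c(c1 = "cost", c2 = "benefit"))
  expect_equal(pf_ideal(one), pfset(c(0.3, 0.6), c(0.5, 0.2),
                                    element = c("c1", "c2")))
  # identical all-benefit rows: the ideal is the common row
  same <- pf_decision_matrix(
    tibble::tibble(alternative = rep(c("A", "B"), each = 2),
                   criterion = rep(c("c1", "c2"), 2),
                   mu = rep(c(0.4, 0.7), 2), nu = rep(c(0.5, 0.1), 2)),
    polarity = c(c1 = "benefit", c2 = "benefit"))
  expect_equal(pf_ideal(same), pfset(c(0.4, 0.7), c(0.5, 0.1),
                                     element = c("c1", "c2")))
})

test_that("the ideal weakly dominates every alternative criterion-wise", {
  withr::local_seed(99)
  for (rep in 1:20) {
    crit <- paste0("c", 1:4)
    pol <- stats::setNames(sample(c("benefit", "cost"), 4, replace = TRUE), crit)
    data <- dplyr::bind_rows(lapply(paste0("a", 1:5), function(a) {
      s <- pf_random(4, seed = sample.int(1e6, 1))
      tibble::tibble(alternative = a, criterion = crit, mu = s$mu, nu = s$nu)
    }))
    mx <- pf_decision_matrix(data, pol)
    ideal <- pf_ideal(mx)
    for (j in seq_along(crit)) {
      cell <- data[data$criterion == crit[j], ]
      if (pol[[j]] == "benefit") {
        expect_true(all(ideal$mu[j] >= cell$mu & ideal$nu[j] <= cell$nu))
      } else {
        expect_true(all(ideal$mu[j] <= cell$mu & ideal$nu[j] >= cell$nu))
      }
    }
  }
})

test_that("medicine ranking reproduces the published best choice and cells", {
  med <- pf_example("medicines")
  r <- pf_rank(med, "grzegorzewski", context = "table6")
  expect_equal(glance(r)$best, "M5")
  expect_within(glance(r)$best_distance, 0.1125, 5e-5)
  r2 <- pf_rank(med, "norm_hamming", context = "table6")
  expect_equal(glance(r2)$best, "M5")
  expect_within(glance(r2)$best_distance, 0.1127, 5e-5)
})

test_that("a row equal to the ideal ranks first at distance zero", {
  med <- pf_example("medicines")
  ideal <- pf_ideal(med)
  extra <- tibble::tibble(alternative = "M0", criterion = ideal$element,
                          mu = ideal$mu, nu = ideal$nu)
  med2 <- pf_decision_matrix(dplyr::bind_rows(extra, tibble::as_tibble(med)),
                             attr(med, "polarity"))
  r <- pf_rank(med2, "chordal", p = 1)
  expect_equal(glance(r)$best, "M0")
  expect_equal(glance(r)$best_distance, 0)
  # and distance to the ideal is zero only for that row
  expect_true(all(tidy(r)$distance[-1] > 0))
})

test_that("sensitivity sweep is rank-stable on the pattern problem", {
  ex <- pf_example("patterns")
  sw <- pf_sweep(ex$prototypes, ex$query, family = "chordal", p_grid = c(1, 2))
  expect_true(attr(sw, "stable"))
  d1 <- dplyr::filter(tidy(sw), p == 1)
  expect_equal(d1$alternative[order(d1$distance)], c("P2", "P1", "P3"))
  expect_within(sort(d1$distance), c(0.1150, 0.3108, 0.3919), 5e-5)
  # single-cell grid is trivially stable
  sw1 <- pf_sweep(ex$prototypes, ex$query, family = "chordal", p_grid = 2)
  expect_true(attr(sw1, "stable"))
})

test_that("lambda = 0 cells are reported degenerate, not invented", {
  ex <- pf_example("patterns")
  sw <- pf_sweep(ex$prototypes, ex$query, family = "nonarch",
                 p_grid = 1, lam_grid = c(0, 0.6))
  deg <- dplyr::filter(tidy(sw), lam == 0)
  expect_true(all(deg$degenerate))
  expect_true(all(is.na(deg$distance)))
  ok <- dplyr::filter(tidy(sw), lam == 0.6)
  expect_false(any(ok$degenerate))
  expect_true(attr(sw, "stable"))  # stability judged on non-degenerate cells
})

test_that("a rank reversal across exponents is detectable", {
  # prototype A is uniformly mediocre, B is excellent on one element and
  # poor on the other: B wins the p = 1 aggregate, A wins the sup-like
  # p = 50 aggregate
  q <- pfset(c(0, 0), c(0, 0), element = c("e1", "e2"))
  protos <- list(A = pfset(c(0.32, 0.32), c(0, 0), element = c("e1", "e2")),
                 B = pfset(c(0.55, 0.03), c(0, 0), element = c("e1", "e2")))
  r1 <- pf_classify(protos, q, "chordal", p = 1)
  r50 <- pf_classify(protos, q, "chordal", p = 50)
  expect_equal(glance(r1)$best, "B")
  expect_equal(glance(r50)$best, "A")
  sw <- pf_sweep(protos, q, family = "chordal", p_grid = c(1, 50))
  expect_false(attr(sw, "stable"))
})

test_that("discrimination report groups the published indistinguishable profiles", {
  profs <- pf_example("profiles")
  rep <- pf_discriminate(profs)
  groups_of <- function(spec_label) {
    d <- dplyr::filter(rep, spec == spec_label, group_size > 1)
    lapply(split(d$label, d$group), sort)
  }
  ham <- groups_of("hamming [table3]")
  expect_true(any(vapply(ham, identical, logical(1),
                         sort(paste("Profile", c(1, 2, 6, 8))))))
  expect_true(any(vapply(ham, identical, logical(1),
                         sort(paste("Profile", c(4, 5, 7, 11))))))
  expect_true(any(vapply(ham, identical, logical(1),
                         sort(paste("Profile", c(9, 10))))))
  # the chordal distance, a sum of two symmetric channel kernels, cannot
  # separate a profile from its mirror: profiles 5 and 8 coincide
  chd <- groups_of("chordal (p = 1)")
  expect_equal(length(chd), 1)
  expect_equal(chd[[1]], sort(paste("Profile", c(5, 8))))
  # repeated identical profiles are always grouped
  twice <- profs[c(1, 1), ]
  rep2 <- pf_discriminate(twice, pf_default_specs()[1, ])
  expect_true(all(rep2$group_size == 2))
})
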