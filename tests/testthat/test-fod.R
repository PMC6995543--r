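test_that("hydrophobicity scales are complete, nonnegative and unit-ranged", {
  for (nm in c("kd_normalized", "rank")) {
    s <- hydrophobicity_scale(nm)
    expect_setequal(names(s), aa_alphabet())
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(range(s), c(0, 1))
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    aa = names(hydrophobicity_scale()), Hr = unname(hydrophobicity_scale())
  ), f)
  expect_equal(read_hydrophobicity_scale(f), hydrophobicity_scale())
})

test_that("effective positions use CA coordinates and skip incomplete residues", {
  cc <- make_fod_case("compliant", n = 25, seed = 4)
  eff <- effective_positions(cc$domain)
  expect_equal(eff$points, atom_xyz(cc$domain, "CA"))
  d <- cc$domain
  d$ca_x[3] <- NA
  d <- domain_structure(d, id = "gap")
  expect_warning(eff2 <- effective_positions(d), "skipping")
  expect_equal(nrow(eff2$points), 24)
  expect_false(3 %in% eff2$index)
  expect_error(effective_positions(cc$domain, mode = "side-chain-centroid"), "unsupported")
})

test_that("theoretical distribution follows the three-sigma Gaussian recipe", {
  # symmetric pair
  expect_equal(
    theoretical_distribution(rbind(c(-3, 0, 0), c(3, 0, 0))),
    c(0.5, 0.5)
  )
  # collinear triple at -d, 0, +d: 1-D Gaussian with sigma = d/3
  d <- 6
  t3 <- theoretical_distribution(rbind(c(-d, 0, 0), c(0, 0, 0), c(d, 0, 0)))
  raw <- c(exp(-4.5), 1, exp(-4.5)) # exp(-d^2 / (2 (d/3)^2)) = exp(-9/2)
  expect_equal(t3, raw / sum(raw), tolerance = 1e-9)
  expect_gt(t3[2], t3[1])
  set.seed(10)
  P <- matrix(rnorm(90, sd = 8), 30, 3)
  expect_equal(sum(theoretical_distribution(P)), 1, tolerance = 1e-12)
  expect_error(theoretical_distribution(matrix(1, 4, 3)), "degenerate spread")
})

test_that("observed distribution implements the contact-kernel sum", {
  scale <- c(A = 0.3, Y = 0.9)
  # far apart: each residue keeps only its self-term 2 Hr_i
  far <- observed_distribution(rbind(c(0, 0, 0), c(100, 0, 0)), c("A", "Y"), scale)
  expect_equal(far, c(0.3, 0.9) / 1.2)
  # coincident points: O_raw_i = 2 h_i + (h_i + h_j), per the kernel formula
  co <- observed_distribution(rbind(c(0, 0, 0), c(0, 0, 0)), c("A", "Y"), scale)
  expect_equal(co, c(3 * 0.3 + 0.9, 3 * 0.9 + 0.3) / (4 * (0.3 + 0.9)))
  eq <- observed_distribution(rbind(c(0, 0, 0), c(0, 0, 0)), c("A", "A"),
    c(A = 0.4, Y = 0)
  )
  expect_equal(eq, c(0.5, 0.5))
  # hand evaluation at an intermediate separation r = 4.5, x = 0.5
  g <- 1 - 0.5 * (7 * 0.25 - 9 * 0.0625 + 5 * 0.5^6 - 0.5^8)
  o_raw <- c(2 * 0.3 + (0.3 + 0.9) * g, 2 * 0.9 + (0.3 + 0.9) * g)
  mid <- observed_distribution(rbind(c(0, 0, 0), c(4.5, 0, 0)), c("A", "Y"), scale)
  expect_equal(mid, o_raw / sum(o_raw), tolerance = 1e-12)
  set.seed(3)
  P <- matrix(rnorm(60, sd = 6), 20, 3)
  aas <- sample(aa_alphabet(), 20, replace = TRUE)
  o <- observed_distribution(P, aas, hydrophobicity_scale())
  expect_equal(sum(o), 1, tolerance = 1e-12)
  expect_true(all(o >= 0))
  expect_error(
    observed_distribution(P, aas, stats::setNames(rep(0, 20), aa_alphabet())),
    "zero hydrophobicity"
  )
})

test_that("T and O are rigid-motion invariant", {
  set.seed(23)
  cc <- make_fod_case("compliant", n = 30, seed = 23)
  t1 <- theoretical_distribution(effective_positions(cc$domain)$points)
  o1 <- observed_distribution(
    effective_positions(cc$domain)$points, cc$aa, cc$scale
  )
  d2 <- transform_domain(cc$domain, random_rotation(), rnorm(3, sd = 20))
  t2 <- theoretical_distribution(effective_positions(d2)$points)
  o2 <- observed_distribution(effective_positions(d2)$points, cc$aa, cc$scale)
  expect_equal(t2, t1, tolerance = 1e-9)
  expect_equal(o2, o1, tolerance = 1e-9)
})

test_that("KL divergence matches hand-evaluated cases", {
  p <- c(0.5, 0.3, 0.2)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  # term-by-term: 0.5 log2(5/6) + 0.3 log2(1) + 0.2 log2(2)
  expect_equal(
    kl_divergence(p, c(0.6, 0.3, 0.1)),
    0.5 * log2(5 / 6) + 0.2,
    tolerance = 1e-12
  )
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "unbounded")
})

test_that("RD has the stated limits and is log-base invariant", {
  t_dens <- c(0.5, 0.3, 0.15, 0.05)
  r_u <- rep(0.25, 4)
  expect_equal(compute_rd(t_dens, t_dens, r_u)$rd, 0)
  expect_equal(compute_rd(r_u, t_dens, r_u)$rd, 1)
  o <- c(0.4, 0.3, 0.2, 0.1)
  rd2 <- compute_rd(o, t_dens, r_u, base = 2)
  rde <- compute_rd(o, t_dens, r_u, base = exp(1))
  expect_equal(rd2$rd, rde$rd, tolerance = 1e-12)
  expect_equal(
    rd2$rd,
    kl_divergence(o, t_dens) / (kl_divergence(o, t_dens) + kl_divergence(o, r_u))
  )
  expect_warning(z <- compute_rd(r_u, r_u, r_u), "coincide")
  expect_equal(z$rd, 0)
})

test_that("RD stays in [0, 1] across random structures", {
  for (s in 1:10) {
    mode <- c("compliant", "anti", "random")[(s %% 3) + 1]
    cc <- make_fod_case(mode, n = 40, seed = s)
    rd <- fod_profile(cc$domain, cc$scale)$rd
    expect_gte(rd, 0)
    expect_lte(rd, 1)
  }
})

test_that("synthetic classes separate around the 0.5 threshold", {
  rds <- vapply(1:12, function(s) {
    c(
      fod_profile(make_fod_case("compliant", n = 60, seed = s)$domain,
        hydrophobicity_scale("rank")
      )$rd,
      fod_profile(make_fod_case("anti", n = 60, seed = s)$domain,
        hydrophobicity_scale("rank")
      )$rd
    )
  }, numeric(2))
  expect_lt(stats::median(rds[1, ]), 0.5)
  expect_gt(stats::median(rds[2, ]), 0.5)
})

test_that("trimming stops immediately on compliant domains", {
  cc <- make_fod_case("compliant", n = 40, seed = 2)
  st <- trim_classify(cc$domain, cc$scale)
  expect_length(st$removal_order, 0)
  expect_true(all(st$status$status == "C"))
  expect_false(st$never_compliant)
  expect_equal(st$original_rd, st$final_rd)
})

test_that("trimming terminates, leaves RD under threshold, removes the plant", {
  fracs <- nrem <- numeric(0)
  for (s in 1:6) {
    case <- plant_polar_core(make_fod_case("compliant", n = 60, seed = s), k = 12)
    st <- trim_classify(case$domain, case$scale)
    expect_lte(length(st$removal_order), 60 - 5)
    if (!st$never_compliant) expect_lt(st$final_rd, 0.5)
    expect_setequal(
      st$status$index[st$status$status == "N"], st$removal_order
    )
    if (length(st$removal_order) > 0) {
      fracs <- c(fracs, mean(st$removal_order %in% case$planted))
      nrem <- c(nrem, length(st$removal_order))
    }
  }
  expect_gt(length(fracs), 0)
  expect_gte(sum(fracs * nrem) / sum(nrem), 0.7)
})

test_that("compliance is monotone in the threshold", {
  case <- plant_polar_core(make_fod_case("compliant", n = 50, seed = 9), k = 10)
  st_strict <- trim_classify(case$domain, case$scale, threshold = 0.3)
  st_loose <- trim_classify(case$domain, case$scale, threshold = 0.7)
  expect_gte(length(st_strict$removal_order), length(st_loose$removal_order))
})

test_that("status runs keep only maximal runs of the minimum length", {
  runs <- status_runs(c("C", "N", "N", "N", "N", "C"), min_len = 4)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$status, "N")
  expect_equal(c(runs$start, runs$end), c(2, 5))
  all_c <- status_runs(rep("C", 10))
  expect_equal(c(all_c$start, all_c$end), c(1, 10))
  expect_equal(nrow(status_runs(rep(c("C", "N"), 5))), 0)
  expect_equal(nrow(status_runs(character(0))), 0)
})

test_that("hydrophobicity profiles are straight lookups", {
  s <- hydrophobicity_scale()
  p <- hydrophobicity_profile("ACDE", s)
  expect_equal(p$hr, unname(s[c("A", "C", "D", "E")]))
  expect_equal(hydrophobicity_profile("AAAA", s)$hr, rep(s[["A"]], 4))
  expect_error(hydrophobicity_profile("AXLL", s), "unknown letter")
})

test_that("the FOD JSON report round-trips its scalars", {
  cc <- make_fod_case("compliant", n = 30, seed = 8)
  prof <- fod_profile(cc$domain, cc$scale)
  st <- trim_classify(cc$domain, cc$scale)
  f <- withr::local_tempfile(fileext = ".json")
  write_fod_report(prof, st, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$rd, prof$rd, tolerance = 1e-12)
  expect_equal(nrow(back$residues), 30)
  expect_true(all(back$residues$status == "C"))
})

test_that("tidy and glance expose the profile tables", {
  cc <- make_fod_case("anti", n = 30, seed = 3)
  prof <- fod_profile(cc$domain, cc$scale)
  expect_equal(nrow(tidy(prof)), 30)
  g <- glance(prof)
  expect_false(g$compliant)
  expect_equal(g$rd, prof$rd)
  expect_equal(sum(tidy(prof)$t_dens), 1, tolerance = 1e-9)
  expect_equal(sum(tidy(prof)$o_dens), 1, tolerance = 1e-9)
})
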