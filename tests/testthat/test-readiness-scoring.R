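test_that("catalytic distance equals the prescribed construction distance", {
  m3 <- make_toy_complex("RRSRSRSRSR", 3.0, seed = 1)
  expect_equal(catalytic_distance(m3), 3.0, tolerance = 1e-6)
  m0 <- make_toy_complex("RRSRSRSRSR", 0, seed = 1)
  expect_equal(catalytic_distance(m0), 0, tolerance = 1e-9)
  m344 <- make_toy_complex("RRSRSRSRSR", 3.44, seed = 2)
  expect_equal(catalytic_distance(m344), 3.44, tolerance = 1e-6)
})

test_that("catalytic distance reports missing atoms and wrong modes", {
  mb <- make_toy_complex("RRSRSRSRSR", mode = "binary", seed = 1)
  expect_error(catalytic_distance(mb), class = "phosready_geometry_error")
  m <- make_toy_complex("RRSRSRSRSR", 3.5, seed = 1)
  m$peptide$atoms <- m$peptide$atoms[m$peptide$atoms$name != "OG", ]
  expect_error(catalytic_distance(m), "OG", class = "phosready_geometry_error")
  m2 <- make_toy_complex("RRSRSRSRSR", 3.5, seed = 1)
  m2$cofactor$atoms <- m2$cofactor$atoms[m2$cofactor$atoms$name != "PG", ]
  expect_error(catalytic_distance(m2), "PG", class = "phosready_geometry_error")
})

test_that("competence classes reproduce the published distance/mobility calls", {
  expect_identical(classify_competence(3.44, 36.5), "competent")
  expect_identical(classify_competence(3.65, 65.8), "transient")
  expect_identical(classify_competence(6.63, 67.9), "displaced")
  expect_identical(classify_competence(3.35, 13.6), "competent")
  expect_identical(classify_competence(3.59, 44.9), "competent")
  expect_error(classify_competence(-1, 10), class = "phosready_input_error")
})

test_that("competence is monotone in distance and mobility", {
  rank <- c(competent = 1, transient = 2, displaced = 3)
  set.seed(12)
  for (i in 1:200) {
    d <- stats::runif(1, 0, 8)
    b <- stats::runif(1, 0, 120)
    base <- rank[[classify_competence(d, b)]]
    expect_gte(rank[[classify_competence(d + stats::runif(1, 0, 4), b)]], base)
    worse_b <- rank[[classify_competence(d, b + stats::runif(1, 0, 60))]]
    if (base == 1) expect_gte(worse_b, base)
    if (base == 3) expect_identical(worse_b, 3)
  }
})

test_that("contact report applies kind-specific cutoffs", {
  m <- make_toy_complex("RRSRSRSRSR", 3.5, seed = 5)
  ct <- contact_report(m)
  expect_identical(nrow(ct), 8L)
  expect_true(all(ct$evaluable))
  expect_true(all(ct$present))
  # salt bridges in the toy are built at 2.8 A tip distance
  expect_true(all(ct$min_distance[ct$kind == "salt_bridge"] <= 4.0))
  # pulling the peptide far away switches every contact off
  far <- m
  far$peptide$atoms[, c("x", "y", "z")] <-
    far$peptide$atoms[, c("x", "y", "z")] + 50
  ct_far <- contact_report(far)
  expect_false(any(ct_far$present))
  # a checklist residue absent from the kinase is flagged, not dropped
  ck <- default_contact_checklist()
  ck$kinase_resno[1] <- 999L
  ct_missing <- contact_report(m, ck)
  expect_false(ct_missing$evaluable[1])
  expect_true(is.na(ct_missing$min_distance[1]))
})

test_that("contact distances match a brute-force all-pairs oracle", {
  m <- make_toy_complex("PSRRSRSRSR", 3.6, seed = 9)
  ct <- contact_report(m)
  kin <- m$kinase$atoms
  pep <- m$peptide$atoms
  resnos <- unique(pep$resno)
  for (i in seq_len(nrow(ct))) {
    ck <- default_contact_checklist()[i, ]
    polar <- ck$kind %in% c("salt_bridge", "h_bond")
    side <- function(a, rn) {
      r <- a[a$resno == rn & !(a$name %in% c("N", "CA", "C", "O")), ]
      if (nrow(r) == 0) r <- a[a$resno == rn & a$name == "CA", ]
      if (polar && any(r$element %in% c("N", "O"))) {
        r <- r[r$element %in% c("N", "O"), ]
      }
      r
    }
    got <- oracle_min_distance(side(kin, ck$kinase_resno),
                               side(pep, resnos[7 + ck$register]))
    expect_equal(ct$min_distance[i], got, tolerance = 1e-12)
  }
})

test_that("contact distances are invariant under rigid motion of the complex", {
  m <- make_toy_complex("RRSRSRSRSR", 3.5, seed = 6)
  base <- contact_report(m)$min_distance
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  moved <- m
  for (comp in c("kinase", "peptide", "tail", "cofactor", "metals", "waters")) {
    a <- moved[[comp]]$atoms
    if (nrow(a) == 0) next
    xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% rot, 2, c(3, -7, 2), "+")
    moved[[comp]]$atoms[, c("x", "y", "z")] <- xyz
  }
  expect_equal(contact_report(moved)$min_distance, base, tolerance = 1e-9)
})

test_that("efficiency-mobility correlation matches the direct formula", {
  expect_equal(efficiency_mobility_correlation(c(10, 20, 30), c(30, 20, 10)), -1)
  expect_equal(efficiency_mobility_correlation(c(1, 5, 9, 11), c(1, 5, 9, 11)), 1)
  set.seed(77)
  x <- stats::runif(100, 0, 100)
  y <- stats::rnorm(100, 50 - 0.4 * x, 10)
  expect_equal(efficiency_mobility_correlation(x, y), oracle_pearson(x, y),
               tolerance = 1e-12)
  # invariance under positive affine maps, sign flip under negation
  r <- efficiency_mobility_correlation(x, y)
  expect_equal(efficiency_mobility_correlation(2 * x + 5, 0.1 * y - 3), r,
               tolerance = 1e-12)
  expect_equal(efficiency_mobility_correlation(-x, y), -r, tolerance = 1e-12)
  expect_error(efficiency_mobility_correlation(rep(1, 5), 1:5),
               class = "phosready_input_error")
  expect_error(efficiency_mobility_correlation(1:2, 2:1),
               class = "phosready_input_error")
})

test_that("readiness report echoes generator ground truth, ordered by site", {
  truth <- data.frame(site = c(84, 78, 82, 80),
                      dist = c(6.6, 3.65, 3.55, 3.5),
                      sigma = c(0.95, 0.95, 0.65, 0.65))
  models <- list()
  profiles <- list()
  seqs <- c(`78` = "PSRRSRSRSR", `80` = "RRSRSRSRSR",
            `82` = "SRSRSRSRSP", `84` = "SRSRSRSPGR")
  for (i in seq_len(nrow(truth))) {
    site <- truth$site[i]
    m <- make_toy_complex(seqs[[as.character(site)]], truth$dist[i],
                          peptide_start_resno = site - 6L,
                          n_kinase_residues = 4L,
                          seed = site, name = sprintf("S%d", site))
    ens <- gaussian_ensemble(m, fluctuation_spec(
      if (truth$sigma[i] < 0.8) "optimal_like" else "weak_like"),
      n_frames = 400, seed = site)
    models[[i]] <- m
    profiles[[i]] <- rmsf_profile(ens)
  }
  rep <- build_report(models, profiles)
  expect_identical(rep$site, sort(truth$site))
  expect_equal(rep$distance_A, truth$dist[order(truth$site)], tolerance = 1e-6)
  # measured O-gamma B-factors sit near their analytic targets
  b_expect <- 8 * pi^2 * truth$sigma[order(truth$site)]^2
  expect_lt(max(abs(rep$og_b_A2 - b_expect) / b_expect), 0.35)
  expect_identical(rep$competence, c("transient", "competent", "competent",
                                     "displaced"))
  # efficiencies attach the correlation
  eff <- data.frame(site = c(78, 80, 82, 84), efficiency = c(40, 90, 85, 25))
  rep2 <- build_report(models, profiles, efficiencies = eff)
  expect_lt(attr(rep2, "correlation"), -0.8)
  # empty input gives an empty, well-formed table
  empty <- build_report(list(), list())
  expect_identical(nrow(empty), 0L)
})
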