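test_that("parameter validation enforces positivity and the AT < GC depth order", {
  expect_error(epbd_parameters(D = c(AT = -0.05, GC = 0.075)), "positive")
  expect_error(epbd_parameters(D = c(AT = 0.08, GC = 0.075)), "hydrogen bonds")
  expect_s3_class(epbd_parameters(D = c(AT = 0.08, GC = 0.075),
                                  allow_inverted_depths = TRUE),
                  "epbd_parameters")
  expect_error(epbd_parameters(k = 0), "positive")
  expect_error(epbd_parameters(rho = -1), "rho")
  # inhomogeneous table must cover all 16 steps
  tab <- stats::setNames(rep(0.025, 15), setdiff(
    as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)), "TT"))
  expect_error(epbd_parameters(k_stack = tab), "TT")
})

test_that("Morse on-site potential matches its closed form", {
  p <- default_params
  expect_equal(onsite_potential(0, "AT", p), 0)
  expect_equal(onsite_potential(0, "GC", p), 0)
  # plateau: within 1e-6 eV of D at y = 100/a
  expect_equal(onsite_potential(100 / p$a[["AT"]], "AT", p), p$D[["AT"]],
               tolerance = 1e-6 / p$D[["AT"]])
  # y = 1/a -> D (e^-1 - 1)^2, against an independently computed constant
  expect_equal(onsite_potential(1 / p$a[["GC"]], "GC", p),
               0.3995764 * p$D[["GC"]], tolerance = 1e-6)
  expect_error(onsite_potential(1, "XY", p), "base class")
})

test_that("stacking potential: zero at equal displacements, harmonic and anharmonic forms", {
  p0 <- epbd_parameters(rho = 0)
  expect_equal(stacking_potential(3.7, 3.7, params = default_params), 0)
  expect_equal(stacking_potential(1, 0, params = p0), 0.0125)
  expect_equal(stacking_potential(1, 0, params = default_params),
               0.0125 * (1 + 2 * exp(-0.35)), tolerance = 1e-12)
  # effective stiffness decreases as both sites open
  w_closed <- stacking_potential(0.1, 0, params = default_params)
  w_open <- stacking_potential(10.1, 10, params = default_params)
  expect_gt(w_closed, w_open)
})

test_that("total potential is additive and zero only at the closed state", {
  p <- default_params
  s2 <- promoter_sequence("AG", 1)  # site 1 AT, site 2 GC, one step
  y <- c(1, 0)
  expect_equal(total_potential(c(0, 0), s2, p), 0)
  expect_equal(total_potential(y, s2, p),
               onsite_potential(1, "AT", p) + onsite_potential(0, "GC", p) +
                 stacking_potential(0, 1, "AG", p))
  expect_error(total_potential(c(1, 2, 3), s2, p), "length")

  # non-negativity with equality iff y == 0, on random states
  s <- make_sequence(sequence_design(length = 12, background_gc = 0.5, seed = 3))
  set.seed(1)
  for (i in 1:25) {
    y <- runif(12, -0.5, 2)
    expect_gt(total_potential(y, s, p), 0)
  }
})

test_that("homopolymer energy is mirror-symmetric", {
  p <- default_params
  s <- promoter_sequence(strrep("A", 8), 4)
  set.seed(2)
  y <- runif(8, -0.3, 1.5)
  expect_equal(total_potential(y, s, p), total_potential(rev(y), s, p))
  # single displaced interior site: force symmetric on the two neighbours
  y1 <- rep(0, 8); y1[4] <- 1.2
  f <- total_force(y1, s, p)
  expect_equal(f[3], f[5])
})

test_that("analytic forces match central-difference gradients to 1e-6 eV/A", {
  p <- default_params
  s <- make_sequence(sequence_design(length = 12, background_gc = 0.5, seed = 9))
  h <- 1e-6
  set.seed(42)
  worst <- 0
  for (rep in 1:100) {
    y <- runif(12, -0.5, 2)
    f <- total_force(y, s, p)
    num <- vapply(1:12, function(i) {
      yp <- y; ym <- y
      yp[i] <- y[i] + h; ym[i] <- y[i] - h
      -(total_potential(yp, s, p) - total_potential(ym, s, p)) / (2 * h)
    }, numeric(1))
    worst <- max(worst, max(abs(f - num)))
  }
  expect_lt(worst, 1e-6)
})

test_that("compiled potential agrees with the R reference", {
  p <- default_params
  s <- make_sequence(sequence_design(length = 15, background_gc = 0.4, seed = 5))
  cls <- base_classes(s)
  D <- unname(p$D[cls]); a <- unname(p$a[cls])
  ks <- rep(p$k, 14)
  set.seed(3)
  for (i in 1:20) {
    y <- runif(15, -0.5, 2)
    expect_equal(dnabreathe:::cpp_total_potential(y, D, a, ks, p$rho, p$beta),
                 total_potential(y, s, p), tolerance = 1e-12)
  }
})

test_that("rho = 0 homogeneous stacking reproduces the harmonic classical model", {
  p0 <- epbd_parameters(rho = 0)
  s <- promoter_sequence("ATGCAT", 3)
  set.seed(4)
  y <- runif(6, -0.3, 1.5)
  cls <- base_classes(s)
  harmonic <- sum(p0$D[cls] * (exp(-p0$a[cls] * y) - 1)^2) +
    sum(p0$k / 2 * diff(y)^2)
  expect_equal(total_potential(y, s, p0), harmonic)
})

test_that("replacing AT by GC never decreases on-site energy at open sites", {
  p <- default_params
  for (y in c(0.05, 0.3, 1, 5)) {
    expect_gte(onsite_potential(y, "GC", p), onsite_potential(y, "AT", p))
  }
})

test_that("inhomogeneous stacking table is honoured when enabled", {
  steps <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  tab <- stats::setNames(seq(0.01, 0.04, length.out = 16), steps)
  p <- epbd_parameters(k_stack = tab)
  expect_equal(stacking_potential(1, 0, "GT", p), tab[["GT"]] / 2 * (1 + 2 * exp(-0.35)))
  s <- promoter_sequence("AG", 1)
  expect_equal(total_potential(c(1, 0), s, p),
               onsite_potential(1, "AT", p) + tab[["AG"]] / 2 * (1 + 2 * exp(-0.35)))
})

test_that("parameter config YAML round-trips", {
  p <- epbd_parameters(D = c(AT = 0.04, GC = 0.09), rho = 1.5, mass = 280)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_epbd_config(p, f)
  q <- read_epbd_config(f)
  expect_equal(q$D, p$D)
  expect_equal(q$rho, p$rho)
  expect_equal(q$mass, p$mass)
})
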