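test_that("spatial_gradients matches analytic derivatives", {
  # linear ramp L(x, y) = x (in column index): gx = 1 interior, gy = 0, gt = 0
  ramp <- matrix(rep(seq_len(32), each = 32), 32, 32)
  g <- spatial_gradients(ramp, ramp, smooth_sigma = 0)
  expect_equal(g$gx[3:30, 3:30, 1], matrix(1, 28, 28))
  expect_equal(g$gy[3:30, 3:30, 1], matrix(0, 28, 28))
  expect_equal(g$gt, array(0, c(32, 32, 1)))

  # uniform temporal step
  g2 <- spatial_gradients(ramp, ramp + 0.3, smooth_sigma = 0)
  expect_equal(g2$gt, array(0.3, c(32, 32, 1)), tolerance = 1e-12)

  # sinusoid: central difference vs closed-form cosine derivative, interior
  x <- seq_len(64)
  L <- matrix(rep(sin(2 * pi * x / 32), each = 64), 64, 64)
  g3 <- spatial_gradients(L, L, smooth_sigma = 0)
  truth <- matrix(rep((2 * pi / 32) * cos(2 * pi * x / 32), each = 64), 64, 64)
  # central differences underestimate by sinc(2*pi/32); compare within 1%
  interior <- 5:60
  expect_equal(g3$gx[interior, interior, 1], truth[interior, interior],
               tolerance = 0.01)

  expect_error(spatial_gradients(ramp, ramp[1:31, ]), "shape")
})

test_that("generator basis has the stated fields and symmetries", {
  b <- make_generator_basis(17, 17)  # odd size: exact center pixel
  dil <- generator_field(b, "dilation")
  rot <- generator_field(b, "rotation")
  expect_identical(c(dil$vx[9, 9], dil$vy[9, 9]), c(0, 0))
  expect_identical(c(rot$vx[9, 9], rot$vy[9, 9]), c(0, 0))

  tx <- generator_field(b, "tx")
  expect_true(all(tx$vx == 1) && all(tx$vy == 0))
  b2 <- make_generator_basis(17, 33, origin = "corner", scale = "pixels")
  ty <- generator_field(b2, "ty")
  expect_true(all(ty$vx == 0) && all(ty$vy == 1))

  # orthogonality of dilation and translation_x over a symmetric grid,
  # verified by direct summation
  expect_equal(sum(dil$vx * tx$vx + dil$vy * tx$vy), 0, tolerance = 1e-12)

  # published shear fields: v_sh1 = (0, x), v_sh2 = (y, 0)
  sh1 <- generator_field(b, "shear1"); sh2 <- generator_field(b, "shear2")
  expect_true(all(sh1$vx == 0) && all(sh2$vy == 0))
  expect_equal(sh1$vy, b$x)
  expect_equal(sh2$vx, b$y)
  # exact linear dependence v_rot = v_sh2 - v_sh1 (the published set is rank 5)
  expect_equal(rot$vx, sh2$vx - sh1$vx)
  expect_equal(rot$vy, sh2$vy - sh1$vy)
})

test_that("assemble_normal_system matches the brute-force double loop", {
  tex <- fixture_texture(16, seed = 3)
  g <- spatial_gradients(tex, tex + 0.01 * fixture_texture(16, seed = 4))
  b <- make_generator_basis(16, 16)
  sys <- assemble_normal_system(g, b)

  # brute-force Gram matrix over u, v by explicit loops over pixels
  keep <- matrix(FALSE, 16, 16); keep[3:14, 3:14] <- TRUE
  GuL <- sapply(c("tx", "ty", "dilation", "rotation", "shear1", "shear2"),
                function(u) {
                  f <- generator_field(b, u)
                  (f$vx * g$gx[, , 1] + f$vy * g$gy[, , 1])[keep]
                })
  S_ref <- matrix(0, 6, 6)
  for (u in 1:6) for (v in 1:6) S_ref[u, v] <- sum(GuL[, u] * GuL[, v])
  H_ref <- -colSums(g$gt[, , 1][keep] * GuL)
  expect_lt(max(abs(sys$S - S_ref)), 1e-10)
  expect_lt(max(abs(sys$H - H_ref)), 1e-10)

  # gt = 0 -> H = 0 exactly; constant frame -> S = H = 0
  g0 <- spatial_gradients(tex, tex)
  expect_identical(as.numeric(assemble_normal_system(g0, b)$H), rep(0, 6))
  flat <- array(0.5, c(16, 16, 1))
  sys_flat <- assemble_normal_system(spatial_gradients(flat, flat), b)
  expect_true(all(sys_flat$S == 0) && all(sys_flat$H == 0))
})

test_that("structural tensor is symmetric positive semi-definite", {
  for (seed in 1:5) {
    p <- fixture_pair("tx", runif(1, -0.5, 0.5), seed = seed)
    g <- spatial_gradients(p$a, p$b)
    S <- assemble_normal_system(g, make_generator_basis(64, 64))$S
    expect_equal(S, t(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 * sum(diag(S))))
  }
})

test_that("solve_motion handles the trivial and degenerate systems", {
  # H = 0, nondegenerate S -> zero vector
  sysd <- list(S = diag(c(5, 4, 3, 2, 1, 1)), H = rep(0, 6))
  expect_equal(as.numeric(solve_motion(sysd)), rep(0, 6))

  # diagonal solve
  sys1 <- list(S = diag(3, 6), H = c(3, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(solve_motion(sys1)), c(1, 0, 0, 0, 0, 0))

  # structureless -> degenerate flag, zeros, no crash
  sys0 <- list(S = matrix(0, 6, 6), H = rep(0, 6))
  p0 <- solve_motion(sys0)
  expect_true(attr(p0, "degenerate"))
  expect_equal(as.numeric(p0), rep(0, 6))

  expect_error(solve_motion(list(S = matrix(rnorm(36), 6), H = rep(1, 6))),
               "symmetric")
  bad <- diag(6); bad[1, 1] <- NaN
  expect_error(solve_motion(list(S = bad, H = rep(1, 6))), "finite")
})

test_that("solve_motion equals the independent pseudo-inverse oracle", {
  set.seed(42)
  cases <- expand.grid(seed = 1:4, nc = c(1L, 3L), amp = c(0.3, -0.6))
  for (i in seq_len(nrow(cases))) {
    gen <- sample(c("tx", "ty", "dilation", "rotation"), 1)
    p <- fixture_pair(gen, cases$amp[i], seed = cases$seed[i],
                      n_channels = cases$nc[i])
    ours <- as.numeric(estimate_motion(p$a, p$b))
    oracle <- oracle_pinv_solve(p$a, p$b)
    expect_lt(max(abs(ours - oracle)), 1e-8)
  }
})

test_that("estimate_motion recovers known warps", {
  p <- fixture_pair("tx", 0.5)
  a <- as.numeric(estimate_motion(p$a, p$b))
  expect_gt(a[1], 0.45); expect_lt(a[1], 0.55)
  expect_true(all(abs(a[-1]) < 0.05))

  # identical frames -> exact zeros
  tex <- fixture_texture(32)
  expect_equal(as.numeric(estimate_motion(tex, tex)), rep(0, 6))

  # small rotation about center (recovered in the minimum-norm gauge:
  # 2/3 of the amplitude on rotation, 1/3 split across the shears; the
  # flow itself is recovered -- check the reconstructed flow matrix)
  pr <- fixture_pair("rotation", 0.4)
  ar <- as.numeric(estimate_motion(pr$a, pr$b))
  b12 <- ar[6] + ar[4]   # coefficient of y in v_x: shear2 + rotation
  b21 <- ar[5] - ar[4]   # coefficient of x in v_y: shear1 - rotation
  expect_equal(b12, 0.4, tolerance = 0.1 * 0.4)
  expect_equal(b21, -0.4, tolerance = 0.1 * 0.4)
  expect_lt(abs(ar[1]), 0.04); expect_lt(abs(ar[2]), 0.04)
})

test_that("channel replication leaves the solution unchanged", {
  p <- fixture_pair("dilation", 0.4)
  a3 <- array(0, c(64, 64, 3))
  b3 <- array(0, c(64, 64, 3))
  for (c in 1:3) { a3[, , c] <- p$a[, , 1]; b3[, , c] <- p$b[, , 1] }
  one <- as.numeric(estimate_motion(p$a, p$b))
  three <- as.numeric(estimate_motion(a3, b3))
  expect_lt(max(abs(one - three)), 1e-10)
})

test_that("horizontal flip transforms parameters by the reflected algebra", {
  # M = diag(-1, 1): tx, rotation, shear1, shear2 negate; ty, dilation invariant
  p <- fixture_pair("ty", 0.4)
  flip <- function(f) f[, rev(seq_len(dim(f)[2])), , drop = FALSE]
  a <- as.numeric(estimate_motion(p$a, p$b))
  af <- as.numeric(estimate_motion(flip(p$a), flip(p$b)))
  signs <- c(-1, 1, 1, -1, -1, -1)
  expect_equal(af, signs * a, tolerance = 1e-6)

  p2 <- fixture_pair("rotation", 0.4)
  a2 <- as.numeric(estimate_motion(p2$a, p2$b))
  af2 <- as.numeric(estimate_motion(flip(p2$a), flip(p2$b)))
  expect_equal(af2, signs * a2, tolerance = 1e-6)
})

test_that("recovered amplitude responds linearly with slope ~1", {
  for (gen in c("tx", "ty", "dilation")) {
    amps <- c(0.2, 0.4, 0.6, 0.8, 1.0)
    rec <- vapply(amps, function(A) {
      p <- fixture_pair(gen, A)
      as.numeric(estimate_motion(p$a, p$b))[match(gen, c("tx", "ty", "dilation",
                                                         "rotation", "shear1", "shear2"))]
    }, numeric(1))
    slope <- coef(lm(rec ~ amps))[["amps"]]
    expect_gt(slope, 0.9); expect_lt(slope, 1.1)
  }
})

test_that("motion_sequence keeps order and flags shape drift", {
  sched <- rep(list(motion_params(tx = 0.2)), 5)
  s <- render_sequence(scene_spec(32, 32, schedule = sched))
  ms <- motion_sequence(s$frames)
  expect_length(ms, 5)

  frames <- s$frames
  frames[[4]] <- frames[[4]][1:31, , , drop = FALSE]
  expect_error(motion_sequence(frames), "frame 4")

  same <- rep(list(fixture_texture(32)), 4)
  zeros <- motion_sequence(same)
  expect_true(all(vapply(zeros, function(p) all(as.numeric(p) == 0), logical(1))))
})

test_that("sequence recovery correlates with the generating schedule", {
  sched <- simulate_motion_schedule(40, onsets = 15, background_sd = 0.05,
                                    transient_amplitude = 6, seed = 9)
  s <- render_sequence(scene_spec(64, 64, schedule = sched$schedule,
                                  texture_seed = 2))
  rec <- motion_matrix(motion_sequence(s$frames))
  for (ch in c(1, 2, 3)) {  # identifiable channels
    expect_gt(cor(rec[ch, ], sched$matrix[ch, ]), 0.95)
  }
})
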