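make_stack <- function(vals_p1, vals_p2, vals_p3) {
  h <- nrow(vals_p1); w <- ncol(vals_p1)
  ones <- matrix(1, h, w); zero <- matrix(0, h, w)
  structure(
    list(channels = list(m00 = ones, D = zero, P = zero, P_S = zero,
                         P1 = vals_p1, P2 = vals_p2, P3 = vals_p3,
                         P_Delta = zero),
         mask = matrix(TRUE, h, w), flagged = matrix(FALSE, h, w),
         height = h, width = w),
    class = "observable_stack"
  )
}

test_that("ROI statistics pool rectangles and floor degenerate deviations", {
  v <- matrix(0.3, 4, 4)
  st <- make_stack(v, v, v)
  cm <- roi_statistics(st, list(rect(0, 0, 4, 4)), "flat", "yellow")
  expect_equal(unname(cm$means), rep(0.3, 3))
  expect_equal(unname(cm$stds), rep(1e-6, 3))  # constant ROI hits the floor
  expect_equal(cm$n_pixels, 16L)

  # hand-computed two-point statistics
  v2 <- matrix(c(0.2, 0.4), 1, 2)
  st2 <- make_stack(v2, v2, v2)
  cm2 <- roi_statistics(st2, list(rect(0, 0, 2, 1)), "pair", "blue")
  expect_equal(unname(cm2$means), rep(0.3, 3))
  expect_equal(unname(cm2$stds), rep(sd(c(0.2, 0.4)), 3), tolerance = 1e-12)
  expect_equal(unname(cm2$stds), rep(0.1414, 3), tolerance = 1e-3)

  # union of two disjoint rectangles equals concatenated pixels
  v3 <- matrix(seq(0.1, 0.9, length.out = 9), 3, 3)
  st3 <- make_stack(v3, v3, v3)
  u <- roi_statistics(st3, list(rect(0, 0, 1, 3), rect(2, 0, 3, 3)),
                      "union", "pink")
  vals <- c(v3[, 1], v3[, 3])
  expect_equal(unname(u$means), rep(mean(vals), 3))
  expect_equal(unname(u$stds), rep(sd(vals), 3))

  expect_error(roi_statistics(st3, list(rect(0, 0, 9, 9)), "oob", "blue"),
               "outside")
  expect_error(roi_statistics(st3, list(rect(2, 2, 2, 3)), "empty", "blue"),
               "empty")
  st_masked <- st3
  st_masked$mask[] <- FALSE
  expect_error(roi_statistics(st_masked, list(rect(0, 0, 3, 3)), "m", "blue"),
               "valid pixels")
})

test_that("Euclidean weights match the distance formula and conserve mass", {
  c1 <- class_model("a", c(0.8, 0.9, 1.0), rep(0.05, 3), "yellow")
  c2 <- class_model("b", c(0.2, 0.3, 0.4), rep(0.05, 3), "blue")

  # at a class mean the weight saturates
  w <- euclidean_weights(c(0.8, 0.9, 1.0), c1, c2)
  expect_equal(unname(w$weights), c(1, 0), tolerance = 1e-12)

  # the worked midpoint example: d1 = d2 = sqrt(3)/2, weights 1/2
  w <- euclidean_weights(c(0.5, 0.6, 0.7), c1, c2)
  expect_equal(unname(w$d_norm), rep(sqrt(3) / 2, 2), tolerance = 1e-12)
  expect_equal(unname(w$weights), c(0.5, 0.5), tolerance = 1e-12)

  # mass conservation and boundedness over random pixels
  set.seed(5)
  P <- matrix(runif(300), 100, 3)
  W <- euclidean_weights(P, c1, c2)
  expect_equal(unname(rowSums(W)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(W >= 0 & W <= 1))

  # swapping the classes permutes the weights
  W2 <- euclidean_weights(P, c2, c1)
  expect_equal(unname(W[, 1]), unname(W2[, 2]), tolerance = 1e-12)
})

test_that("degenerate class means are dropped or rejected", {
  c1 <- class_model("a", c(0.5, 0.9, 1.0), rep(0.05, 3), "yellow")
  c2 <- class_model("b", c(0.5, 0.3, 0.4), rep(0.05, 3), "blue")
  expect_warning(w <- euclidean_weights(c(0.9, 0.9, 1.0), c1, c2), "dropped")
  expect_equal(unname(w$weights), c(1, 0), tolerance = 1e-12)

  c3 <- class_model("c", c(0.5, 0.9, 1.0), rep(0.05, 3), "pink")
  expect_error(euclidean_weights(c(0.5, 0.5, 0.5), c1, c3), "indistinguishable")
})

test_that("Euclidean pseudo-color mixes class colors and blacks out the mask", {
  v <- matrix(c(0.8, 0.5, 0.2, 0.2), 2, 2)  # one pixel per regime
  st <- make_stack(v, v + 0.1, v + 0.2)
  c1 <- class_model("hi", c(0.8, 0.9, 1.0), rep(0.05, 3), "yellow")
  c2 <- class_model("lo", c(0.2, 0.3, 0.4), rep(0.05, 3), "blue")
  st$mask[2, 2] <- FALSE
  pc <- euclidean_pseudocolor(st, c1, c2)
  expect_s3_class(pc, "pseudocolor_image")
  expect_equal(pc$rgb[1, 1, ], c(1, 1, 0), tolerance = 1e-12)      # class 1 color
  expect_equal(pc$rgb[2, 1, ], c(0.5, 0.5, 0.5), tolerance = 1e-12) # equidistant
  expect_equal(pc$rgb[1, 2, ], c(0, 0, 1), tolerance = 1e-12)      # class 2 color
  expect_equal(pc$rgb[2, 2, ], c(0, 0, 0))                          # masked
  expect_true(all(pc$rgb >= 0 & pc$rgb <= 1))

  # symmetry: swapping the classes leaves the rendered image unchanged
  pc2 <- euclidean_pseudocolor(st, c2, c1)
  expect_equal(pc$rgb, pc2$rgb, tolerance = 1e-12)
})

test_that("Gaussian membership follows the product-of-exponentials rule", {
  cl <- class_model("a", rep(0.5, 3), rep(0.1, 3), "pink")
  expect_equal(normal_probability(rep(0.5, 3), cl), 1)
  expect_equal(normal_probability(rep(0.6, 3), cl), exp(-3), tolerance = 1e-12)
  expect_equal(normal_probability(c(0.6, 0.5, 0.5), cl), exp(-1),
               tolerance = 1e-12)
  # z = 10 per channel: numerically black
  expect_lt(normal_probability(rep(1.5, 3), cl), 1e-100)

  # bounded in [0, 1] with the maximum only at the means
  set.seed(9)
  P <- matrix(runif(3000), 1000, 3)
  pr <- normal_probability(P, cl)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(pr[rowSums(abs(P - 0.5)) > 1e-6] < 1))

  # strict monotonicity in each |p_j - m_j|, others held fixed
  for (j in 1:3) {
    for (sgn in c(-1, 1)) {
      steps <- sapply(seq(0, 0.3, by = 0.05), function(dd) {
        p <- c(0.55, 0.45, 0.5); p[j] <- cl$means[j] + sgn * dd
        normal_probability(p, cl)
      })
      expect_true(all(diff(steps) < 0))
    }
  }
})

test_that("Normal pseudo-color sums class contributions, clips and classifies", {
  v <- matrix(c(0.5, 0.5), 1, 2)
  st <- make_stack(v, v, v)
  cl <- class_model("one", rep(0.5, 3), rep(0.1, 3), c(0, 1, 0.5))
  pc <- normal_pseudocolor(st, list(cl))
  expect_equal(pc$rgb[1, 1, ], c(0, 1, 0.5), tolerance = 1e-12)

  # two classes both at probability 1: channel sums clip at 1
  cl1 <- class_model("p", rep(0.5, 3), rep(0.1, 3), c(1, 0, 0.5))
  cl2 <- class_model("g", rep(0.5, 3), rep(0.1, 3), c(0, 1, 0.5))
  pc2 <- normal_pseudocolor(st, list(cl1, cl2), unclipped = TRUE)
  expect_equal(pc2$raw[1, 1, ], c(1, 1, 1))
  expect_equal(pc2$rgb[1, 1, ], c(1, 1, 1))

  # a pixel far from every class renders black without any threshold
  far <- make_stack(matrix(0.99, 1, 1), matrix(0.99, 1, 1), matrix(0.99, 1, 1))
  pcf <- normal_pseudocolor(far, list(cl1, cl2))
  expect_equal(pcf$rgb[1, 1, ], c(0, 0, 0), tolerance = 1e-20)

  # argmax labels with an unassigned threshold
  v3 <- matrix(c(0.5, 0.8, 0.99), 1, 3)
  st3 <- make_stack(v3, v3, v3)
  clA <- class_model("A", rep(0.5, 3), rep(0.1, 3), "yellow")
  clB <- class_model("B", rep(0.8, 3), rep(0.1, 3), "blue")
  pc3 <- normal_pseudocolor(st3, list(clA, clB))
  lab <- classify_pixels(pc3, threshold = 1e-3)
  expect_equal(as.vector(lab), c(1L, 2L, 0L))
  expect_error(classify_pixels(euclidean_pseudocolor(st3, clA, clB)),
               "Normal")

  expect_error(normal_pseudocolor(st3, list()), "at least one")
})

test_that("class models validate their inputs", {
  expect_error(class_model("x", 1:3 / 10, rep(0.1, 3), c(2, 0, 0)), "\\[0, 1\\]")
  expect_error(class_model("x", 1:3 / 10, rep(0.1, 3), "mauve"), "preset")
  cm <- class_model("x", 1:3 / 10, c(0, 0.1, 0), "yellow")
  expect_equal(unname(cm$stds), c(1e-6, 0.1, 1e-6))  # flooring
  expect_error(
    euclidean_weights(c(0.5, 0.5, 0.5),
                      class_model("a", 1:3 / 10, rep(0.1, 3), "yellow",
                                  triplet = "ipp"),
                      class_model("b", 3:1 / 10, rep(0.1, 3), "blue",
                                  triplet = "cp")),
    "different observable triplets")
})
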