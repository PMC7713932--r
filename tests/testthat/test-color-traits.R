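test_that("channel modes obey the tie rule and ignore unmasked pixels", {
  pix <- array(rep(c(10, 20, 30), each = 4), dim = c(2, 2, 3))
  expect_equal(mode_channel(pix, channel = "red"), 10)
  expect_equal(mode_channel(pix, channel = "total"), 60)

  two <- array(0L, dim = c(1, 2, 3)); two[1, 2, ] <- 255L
  expect_equal(mode_channel(two, channel = "blue"), 0)   # tie -> smallest

  # unmasked pixels must not matter, nor pixel order
  fx <- sim_wing_region(c(120, 40, 200), 0.2, c(30, 30), seed = 4)
  m2 <- fx$mask; m2[1:10, ] <- FALSE
  fx$pixels[1:10, , ] <- 255L
  expect_equal(mode_channel(fx$pixels, m2, "blue"), 200)

  expect_error(mode_channel(pix, matrix(FALSE, 2, 2), "red"), "no pixels")
})

test_that("synthetic fixtures recover their true mode at 30% noise", {
  fx <- sim_wing_region(c(200, 30, 40), 0.3, c(100, 100), seed = 1)
  expect_equal(mode_channel(fx, channel = "red"), 200)
  expect_equal(mode_channel(fx, channel = "green"), 30)
  expect_equal(mode_channel(fx, channel = "blue"), 40)
  expect_equal(mode_channel(fx, channel = "total"), 270)
})

test_that("species aggregation averages specimen modes and demands full coverage", {
  masks <- list(wing = matrix(TRUE, 5, 5), cell1 = matrix(TRUE, 5, 5),
                cell2 = matrix(TRUE, 5, 5), cell3 = matrix(TRUE, 5, 5))
  mk <- function(v) array(rep(v, each = 25), dim = c(5, 5, 3))
  m1 <- measure_specimen(mk(c(100, 50, 20)), masks, "sp1", "a")
  m2 <- measure_specimen(mk(c(120, 50, 20)), masks, "sp1", "b")
  m3 <- measure_specimen(mk(c(10, 10, 10)), masks, "sp2", "c")
  tab <- aggregate_species(rbind(m1, m2, m3), c("sp1", "sp2"))
  expect_equal(dim(tab), c(2L, 17L))             # species + 16 traits
  expect_equal(tab["sp1", "wing_red"], 110)
  expect_equal(tab["sp2", "cell3_total"], 30)
  # specimen order must not matter
  tab2 <- aggregate_species(rbind(m3, m2, m1), c("sp1", "sp2"))
  expect_identical(tab, tab2)
  expect_error(aggregate_species(rbind(m1, m2), c("sp1", "sp2")),
               "zero specimens")
})

test_that("lightness index returns zero-sum OLS residuals with expected variance", {
  set.seed(20)
  n <- 100
  light3 <- runif(n, 50, 200)        # wing lightness = mode_total / 3
  tab <- data.frame(species = paste0("s", 1:n))
  for (r in c("wing", "cell1", "cell2", "cell3")) {
    tot <- round(light3 * 3)
    tab[[paste0(r, "_total")]] <- tot
    tab[[paste0(r, "_red")]] <- round(light3 * 1.2)       # pure lightness
    tab[[paste0(r, "_green")]] <- round(runif(n, 0, 255))
    tab[[paste0(r, "_blue")]] <- 2 * (tot / 3) + rnorm(n) # slope 2 + noise
  }
  rownames(tab) <- tab$species
  li <- lightness_index(tab)
  expect_equal(ncol(li), 12L)
  expect_true(all(abs(colSums(li)) < 1e-8))
  # a trait proportional to lightness has (near) zero residuals
  expect_lt(max(abs(li$wing_red_resid)), 1)      # rounding noise only
  # residual variance of the blue trait tracks its noise variance (1)
  expect_lt(abs(var(li$wing_blue_resid) - 1) / 1, 0.3)
  tab$wing_total <- 90
  expect_error(lightness_index(tab), "constant lightness")
})

test_that("PNG round trip preserves pixels and masks", {
  fx <- sim_wing_region(c(17, 230, 99), 0.1, c(16, 16), seed = 2)
  f <- tempfile(fileext = ".png")
  write_wing_image(fx$pixels, f)
  back <- read_wing_image(f)
  expect_identical(back, fx$pixels)
  mf <- tempfile(fileext = ".png")
  png::writePNG(matrix(as.numeric(fx$mask), 16, 16), mf)
  expect_identical(read_region_mask(mf), fx$mask)
})
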