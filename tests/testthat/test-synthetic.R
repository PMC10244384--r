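test_that("panel generation is deterministic and honors the class split", {
  s <- panel_spec(10, high_fraction = 0.5, seed = 1)
  gen <- generate_panel(s)
  expect_equal(nrow(gen$panel), 10)
  expect_equal(sum(gen$panel$halflife_s > 60), 5)
  expect_equal(sum(gen$panel$label), 5)

  gen2 <- generate_panel(panel_spec(200, seed = 7))
  gen3 <- generate_panel(panel_spec(200, seed = 7))
  expect_identical(gen2, gen3)
  expect_false(identical(gen2$panel$cdr3b,
                         generate_panel(panel_spec(200, seed = 8))$panel$cdr3b))
})

test_that("an empty panel is returned without error", {
  gen <- generate_panel(panel_spec(0))
  expect_equal(nrow(gen$panel), 0)
  expect_equal(nrow(gen$exposures), 0)
})

test_that("generated half-lives respect their class interval around 60 s", {
  gen <- generate_panel(panel_spec(150, high_fraction = 0.3, seed = 2))
  hi <- gen$panel$halflife_s[gen$panel$label == 1]
  lo <- gen$panel$halflife_s[gen$panel$label == 0]
  expect_true(all(hi > 60) && all(hi >= 65) && all(hi <= 250))
  expect_true(all(lo < 60) && all(lo >= 0.5) && all(lo <= 55))
  # exposure fractions are valid and one profile per clonotype position
  expect_true(all(gen$exposures$exposed_fraction >= 0 &
                    gen$exposures$exposed_fraction <= 1))
  lens <- nchar(gen$panel$cdr3b)
  expect_equal(unname(table(gen$exposures$tcr_id)[gen$panel$tcr_id]),
               lens, ignore_attr = TRUE)
})

test_that("invalid panel specs are rejected", {
  expect_error(panel_spec(5, cdr3_length_range = c(9, 15)), ">= 11")
  expect_error(panel_spec(5, halflife_low = c(1, 70)), "60 s")
  expect_error(panel_spec(5, halflife_high = c(50, 70)), "60 s")
  expect_error(panel_spec(5, high_fraction = 1.2))
})

test_that("contact tables follow the linear model exactly when noiseless", {
  spec <- contact_spec(1, noise_sd = 0)
  tab <- generate_contacts(spec, n_apolar = 30, n_polar = 5)
  expect_equal(tab$halflife_s, 60.255)
  tab0 <- generate_contacts(contact_spec(1, noise_sd = 0),
                            n_apolar = 0, n_polar = 0)
  expect_equal(tab0$halflife_s, -62.89)
  # residuals identically zero on a whole table
  tab10 <- generate_contacts(contact_spec(10, noise_sd = 0, seed = 5))
  expect_equal(tab10$halflife_s,
               -62.89 + 2.647 * tab10$n_apolar + 8.747 * tab10$n_polar)
  # determinism with noise
  a <- generate_contacts(contact_spec(10, noise_sd = 5, seed = 3))
  b <- generate_contacts(contact_spec(10, noise_sd = 5, seed = 3))
  expect_identical(a, b)
})

test_that("repertoire sampling responds to the tumor bias", {
  gen <- generate_panel(panel_spec(40, high_fraction = 0.25, seed = 9))
  expect_error(generate_repertoires(gen$panel, depth = 0), "depth")

  # infinite bias: tumor contains only high-labelled clonotypes
  reps <- generate_repertoires(gen$panel, tumor_high_bias = Inf, depth = 5000,
                               seed = 10)
  expect_true(all(reps$tumor$label == 1))
  expect_true(any(reps$blood$label == 0))

  # bias = 1: compartments exchangeable; bias = 3: tumor enriched
  pct <- function(df) 100 * sum(df$count[df$label == 1]) / sum(df$count)
  d1 <- d3 <- numeric(100)
  for (s in 1:100) {
    r1 <- generate_repertoires(gen$panel, 1, depth = 10000, seed = 200 + s)
    r3 <- generate_repertoires(gen$panel, 3, depth = 10000, seed = 200 + s)
    d1[s] <- pct(r1$tumor) - pct(r1$blood)
    d3[s] <- pct(r3$tumor) - pct(r3$blood)
  }
  expect_lt(abs(mean(d1)), 1)     # exchangeable: mean difference near 0
  expect_gt(mean(d3), 10)         # biased: tumor clearly enriched
})

test_that("logistic panels plant the requested signal", {
  fdef <- feature_definition(c("R", "N", "D"))
  gp <- generate_logistic_panel(500, fdef, b0 = -1, weights = c(2, 2, -2),
                                seed = 11)
  expect_equal(nrow(gp$panel), 500)
  expect_equal(dim(gp$features), c(500, 3))
  # higher planted probability -> higher empirical label rate
  hi_half <- gp$prob > stats::median(gp$prob)
  expect_gt(mean(gp$panel$label[hi_half]), mean(gp$panel$label[!hi_half]))
})
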