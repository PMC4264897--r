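test_that("Pearson correlation rows match the closed-form t and handle edge cases", {
  p <- pearson_cor(c(1, 2, 3), c(1, 3, 2))
  expect_equal(p$r, 0.5, tolerance = 1e-12)
  expect_equal(p$t, 0.5 * sqrt((3 - 2) / (1 - 0.25)), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    pc <- pearson_cor(x, y)
    r_o <- pearson_oracle(x, y)
    expect_equal(pc$r, r_o, tolerance = 1e-12)
    expect_equal(pc$t, r_o * sqrt(13 / (1 - r_o^2)), tolerance = 1e-10)
    expect_equal(pc$p_value, 2 * pt(-abs(pc$t), 13), tolerance = 1e-12)
  }
  exact <- pearson_cor(1:5, 2 * (1:5) + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$p_value, 0)
  undef <- pearson_cor(rep(1, 5), rnorm(5))
  expect_true(is.na(undef$r) && is.na(undef$p_value))
})

test_that("component-size tables cross components, sizes and groups with stable shape", {
  # isometric construction: every absolute component proportional to mass
  set.seed(42)
  M <- exp(rnorm(60, -1.2, 0.3))
  d <- suppressWarnings(as_morph_data(data.frame(
    id = sprintf("i%02d", 1:60), sex = rep(c("female", "male"), 30),
    fresh_mass = M, pronotum = M^(1 / 2.6) * 3,
    dry_mass = 0.3 * M, lean_dry_mass = 0.25 * M)))
  tab <- suppressWarnings(component_size_table(d))
  # tibia/femur are absent and skipped
  expect_warning(component_size_table(d), "tibia")
  expect_false(any(tab$size_or_index %in% c("tibia", "femur")))
  expect_setequal(unique(tab$group), c("pooled", "female", "male"))
  abs_mass <- tab[tab$component == "dry_mass" & tab$size_or_index == "fresh_mass", ]
  expect_true(all(abs_mass$r > 0.999))
  expect_true(all(abs_mass$significant))
  # exactly proportional components make the percentage forms constant:
  # those cells are reported as undefined, never dropped
  pd <- tab[tab$component == "pct_dry_mass" & tab$group == "pooled", ]
  expect_true(all(is.na(pd$r)) && all(is.na(pd$significant)))
  expect_equal(nrow(tab), 4 * 2 * 2 * 3)   # components x forms x sizes x groups

  # with a noisy dry-mass share, relative dry and relative water mirror each
  # other exactly because water = fresh - dry
  d2 <- d
  d2$dry_mass <- (0.3 + runif(60, -0.03, 0.03)) * M
  d2 <- suppressWarnings(as_morph_data(as.data.frame(d2)[
    setdiff(names(d2), c("water_mass", "fat_mass", "flagged", "flag_reason"))]))
  tab2 <- suppressWarnings(component_size_table(d2))
  pd2 <- tab2[tab2$component == "pct_dry_mass" & tab2$group == "pooled", ]
  pw2 <- tab2[tab2$component == "pct_water_mass" & tab2$group == "pooled", ]
  expect_equal(pd2$r, -pw2$r[match(pd2$size_or_index, pw2$size_or_index)],
               tolerance = 1e-10)
})

test_that("single-sex data emit only that sex's per-group rows", {
  set.seed(43)
  d <- rand_logpairs(n = 12)
  pop <- morph_from_logpairs(d$x, d$y, sex = "female",
                             dry_mass = 0.3 * exp(d$y),
                             lean_dry_mass = 0.2 * exp(d$y))
  tab <- suppressWarnings(component_size_table(pop))
  expect_setequal(unique(tab$group), c("pooled", "female"))
})

test_that("index-component tables align by id and flag exact relationships", {
  cfg <- synth_preset("reference_gtex")
  pop <- quiet_pop(cfg, seed = 44)
  L0 <- reference_length(pop)
  smi <- scaled_mass_index(pop, 2.642, L0)
  # a scaled component identical to the index correlates perfectly
  fake <- data.frame(id = smi$id, scaled = smi$smi)
  tab <- index_component_table(smi, list(self = fake), sex = pop$sex)
  expect_equal(tab$r[tab$group == "pooled"], 1)
  expect_setequal(unique(tab$group), c("pooled", "female", "male"))
  # id mismatch is an explicit error
  bad <- fake; bad$id[1] <- "not_there"
  expect_error(index_component_table(smi, list(self = bad)), "id mismatch")
  # constant component: undefined correlation is reported as such
  const <- data.frame(id = smi$id, scaled = 1)
  tabc <- index_component_table(smi, list(const = const))
  expect_true(is.na(tabc$r))
})

test_that("uncoupled fat shows no practically meaningful index correlation; coupled fat favors the SMI", {
  # with the condition signal entering mass but not fat, both indices'
  # correlations with scaled fat stay near zero (the reference-population
  # regime); with fat coupled to condition the SMI correlates more strongly
  # than the residual index because the OLS slope under-corrects for size
  mk <- function(rho) {
    g <- data.frame(name = c("female", "male"), sex = c("female", "male"),
                    n = c(103L, 86L), alpha = c(-4.388, -4.408),
                    mu_logL = 1.2066, sigma_logL = 0.06,
                    stringsAsFactors = FALSE)
    synth_config(g, 2.642, 0.07, sqrt(0.07^2 + 0.02^2) / 2.642, 0.02,
                 rho_fat_cond = rho)
  }
  run <- function(rho, n_rep, policy) {
    out <- matrix(0, n_rep, 2)
    cfg <- mk(rho)
    for (i in seq_len(n_rep)) {
      pop <- quiet_pop(cfg, seed = 300000 + i)
      L0 <- reference_length(pop)
      smi <- scaled_mass_index(pop, 2.642, L0)
      ri <- residual_index(pop)
      fat <- suppressWarnings(scale_component(pop, "fat_mass", L0 = L0,
                                              exponent_policy = policy,
                                              b_sma = 2.642))
      idx <- merge(smi, ri, by = "id")
      tab <- index_component_table(idx, list(fat_mass = fat))
      out[i, ] <- c(tab$r[tab$size_or_index == "smi"],
                    tab$r[tab$size_or_index == "residual_index"])
    }
    colMeans(out)
  }
  r0 <- run(0, 200, "body_mass")
  expect_lt(abs(r0[1]), 0.15)
  expect_lt(abs(r0[2]), 0.15)
  r6 <- run(0.6, 500, "component_specific")
  expect_gt(r6[1], r6[2])   # SMI beats the residual index on coupled fat
  expect_gt(r6[1], 0.3)
})
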