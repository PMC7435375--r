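cfg <- default_fis_config()
core_pts <- list(perclos = c(Low = 0.05, Medium = 0.225, High = 0.5),
                 ecd = c(Low = 0.25, Medium = 2.25, High = 10),
                 aot = c(Low = 0.5, Medium = 4, High = 10))

test_that("membership functions are 1 on the core and linear on the flanks", {
  mf <- membership_function("trapezoidal", c(0.1, 0.2, 0.25, 0.35))
  expect_equal(mf_eval(mf, c(0.2, 0.225, 0.25)), c(1, 1, 1))
  expect_equal(mf_eval(mf, 0.15), 0.5)
  expect_equal(mf_eval(mf, c(0.05, 0.4)), c(0, 0))
  tri <- membership_function("triangular", c(0, 1, 2))
  expect_equal(mf_eval(tri, c(0, 0.5, 1, 1.5, 2)), c(0, 0.5, 1, 0.5, 0))
  # shoulder terms attain 1 at the universe edge
  sh <- membership_function("trapezoidal", c(0, 0, 0.1, 0.2))
  expect_equal(mf_eval(sh, 0), 1)
  expect_error(membership_function("trapezoidal", c(0.3, 0.2, 0.4, 0.5)),
               "non-decreasing")
})

test_that("fuzzification clamps to the universe and splits crossovers evenly", {
  v <- cfg$variables$perclos
  expect_equal(unname(fuzzify(0.05, v)), c(1, 0, 0))
  d <- fuzzify(0.15, v)  # Low/Medium crossover
  expect_equal(unname(d["Low"]), unname(d["Medium"]))
  expect_equal(unname(d["Low"]), 0.5)
  expect_equal(fuzzify(-0.2, v), fuzzify(0, v))
  expect_equal(fuzzify(1.7, v), fuzzify(1, v))
})

test_that("rule evaluation uses min for AND and max for aggregation", {
  crisp <- function(term) setNames(as.numeric(.levels_test == term), .levels_test)
  agg <- evaluate_rules(list(perclos = crisp("Low"), ecd = crisp("Low"),
                             aot = crisp("Low")), cfg$rule_base)
  expect_equal(unname(agg), c(1, 0, 0))
  agg <- evaluate_rules(list(perclos = crisp("High"), ecd = crisp("Low"),
                             aot = crisp("Low")), cfg$rule_base)
  expect_equal(names(which.max(agg)), "Medium")
  agg <- evaluate_rules(list(perclos = crisp("Low"), ecd = crisp("Medium"),
                             aot = crisp("High")), cfg$rule_base)
  expect_equal(names(which.max(agg)), "Medium")
  # partial degrees: the firing strength is the min across antecedents
  deg <- list(perclos = c(Low = 0.8, Medium = 0.2, High = 0),
              ecd = c(Low = 0.6, Medium = 0.4, High = 0),
              aot = c(Low = 1, Medium = 0, High = 0))
  agg <- evaluate_rules(deg, cfg$rule_base)
  expect_equal(unname(agg["Low"]), 0.6)     # rule (L,L,L) fires at min(0.8, 0.6, 1)
  expect_equal(unname(agg["Medium"]), 0.2)  # best Medium rule is (M,M,L)
})

test_that("min-of-max defuzzification breaks ties toward the smaller singleton", {
  s <- c(Low = 0, Medium = 0.5, High = 1)
  expect_equal(defuzzify_min_of_max(c(Low = 0.2, Medium = 0.7, High = 0.4), s)$label,
               "Medium")
  tie <- defuzzify_min_of_max(c(Low = 0.2, Medium = 0.7, High = 0.7), s)
  expect_equal(tie$label, "Medium")
  expect_equal(tie$crisp, 0.5)
  lone <- defuzzify_min_of_max(c(Low = 1, Medium = 0, High = 0), s)
  expect_equal(lone$label, "Low")
  expect_equal(lone$crisp, 0)
  expect_equal(unname(lone$memberships["Low"]), 1)
  expect_error(defuzzify_min_of_max(c(Low = 0, Medium = 0, High = 0), s),
               "no rule fired")
  # brute-force over orderings: the winner always attains the max degree and
  # has the smallest singleton among the argmax set
  set.seed(5)
  for (i in 1:50) {
    d <- round(setNames(runif(3), names(s)), 2)
    if (max(d) == 0) next
    out <- defuzzify_min_of_max(d, s)
    expect_equal(unname(d[out$label]), max(d))
    argmax <- names(d)[d == max(d)]
    expect_equal(out$crisp, min(s[argmax]))
  }
})

test_that("inference reduces to the crisp rule table at term cores", {
  for (P in .levels_test) for (E in .levels_test) for (A in .levels_test) {
    lev <- infer(core_pts$perclos[P], core_pts$ecd[E], core_pts$aot[A], cfg)
    expect_equal(lev$label, rule_lookup(cfg$rule_base, P, E, A),
                 info = paste(P, E, A))
  }
})

test_that("prose-anchored rule semantics hold", {
  at <- function(P, E, A) infer(core_pts$perclos[P], core_pts$ecd[E],
                                core_pts$aot[A], cfg)$label
  expect_equal(infer(0, 0, 0, cfg)$label, "Low")
  expect_equal(at("High", "Low", "Low"), "Medium")   # one eye indicator high
  expect_equal(at("Low", "High", "Low"), "Medium")
  expect_equal(at("Medium", "Medium", "Low"), "Medium")  # two eye indicators medium
  expect_equal(at("Medium", "Low", "High"), "Medium")    # AOT high + another medium
  expect_equal(at("Low", "Medium", "High"), "Medium")
  expect_equal(at("Low", "Low", "High"), "Low")  # AOT-alone inertness (talking/singing)
})

test_that("rule-base validation reports totality and monotonicity violations", {
  full <- default_rule_base()$rules
  expect_error(rule_base(full[-5, ]), "no rule for antecedent")
  bad <- full
  bad$output[bad$perclos == "High" & bad$ecd == "High" & bad$aot == "High"] <- "Low"
  expect_error(rule_base(bad), "non-monotone")
  dup <- rbind(full, full[1, ])
  expect_error(rule_base(dup), "duplicate")
})

test_that("FIS config round-trips through YAML and the shipped default loads", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fis_config(cfg, path)
  cfg2 <- read_fis_config(path)
  expect_identical(cfg2, cfg)
  shipped <- system.file("extdata", "fis_default.yaml", package = "drowsefis")
  expect_true(nzchar(shipped))
  expect_identical(read_fis_config(shipped), cfg)
  expect_error(fis_config(cfg$variables, cfg$rule_base,
                          c(Low = 0.5, Medium = 0.5, High = 1)),
               "strictly increasing")
})

test_that("output level is monotone in each input over a dense grid", {
  g <- list(p = seq(0, 1, length.out = 20), e = seq(0, 60, length.out = 20),
            a = seq(0, 60, length.out = 20))
  grid <- expand.grid(p = g$p, e = g$e, a = g$a)
  lv <- infer_series(data.frame(t = seq_len(nrow(grid)), perclos = grid$p,
                                ecd = grid$e, aot = grid$a), cfg)
  arr <- array(match(lv$label, .levels_test), dim = c(20, 20, 20))
  expect_false(any(apply(arr, c(2, 3), function(v) any(diff(v) < 0))))
  expect_false(any(apply(arr, c(1, 3), function(v) any(diff(v) < 0))))
  expect_false(any(apply(arr, c(1, 2), function(v) any(diff(v) < 0))))
  # totality: a label for every grid point
  expect_false(anyNA(lv$label))
})
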