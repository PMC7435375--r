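# Mamdani fuzzy inference: (PERCLOS, ECD, AOT) -> three-level drowsiness.
# AND connective and implication = minimum; aggregation = maximum; output terms
# are singletons; defuzzification = minimum of maximum (smallest singleton
# among the output terms attaining the maximal aggregated degree).

.fis_vars <- c("perclos", "ecd", "aot")

#' Piecewise-linear membership function
#'
#' @param shape `"triangular"` (3 breakpoints) or `"trapezoidal"` (4).
#' @param breakpoints non-decreasing abscissae in the variable's units;
#'   equal breakpoints make shoulder (one-sided) terms.
#' @return object of class `membership_function`.
#' @export
membership_function <- function(shape = c("trapezoidal", "triangular"), breakpoints) {
  shape <- match.arg(shape)
  need <- if (shape == "triangular") 3L else 4L
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != need) {
    .stopf("%s membership function needs %d breakpoints", shape, need)
  }
  if (is.unsorted(breakpoints)) .stopf("breakpoints must be non-decreasing")
  structure(list(shape = shape, breakpoints = breakpoints),
            class = "membership_function")
}

#' Evaluate a membership function
#'
#' @param mf a [membership_function()].
#' @param x numeric vector.
#' @return degrees in `[0, 1]`, 1 on the core.
#' @export
mf_eval <- function(mf, x) {
  bp <- mf$breakpoints
  if (mf$shape == "triangular") bp <- bp[c(1, 2, 2, 3)]
  a <- bp[1]; b <- bp[2]; cc <- bp[3]; d <- bp[4]
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
  dn <- if (d > cc) (d - x) / (d - cc) else as.numeric(x <= d)
  pmax(0, pmin(up, 1, dn))
}

#' Fuzzy input variable
#'
#' @param name one of `"perclos"`, `"ecd"`, `"aot"`.
#' @param universe numeric `c(lo, hi)` in the indicator's units.
#' @param terms named list of [membership_function()]s for `Low`, `Medium`,
#'   `High`; cores must be ordered Low < Medium < High and every universe
#'   point must have positive membership in at least one term.
#' @return object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, universe, terms) {
  name <- match.arg(name, .fis_vars)
  if (length(universe) != 2L || universe[1] >= universe[2]) {
    .stopf("universe must be c(lo, hi) with lo < hi")
  }
  if (!identical(sort(names(terms)), sort(.levels))) {
    .stopf("variable '%s' needs exactly the terms Low, Medium, High", name)
  }
  v <- structure(list(name = name, universe = as.numeric(universe),
                      terms = terms[.levels]),
                 class = "fuzzy_variable")
  grid <- seq(universe[1], universe[2], length.out = 201)
  deg <- vapply(v$terms, mf_eval, numeric(length(grid)), x = grid)
  if (any(apply(deg, 1, max) <= 0)) {
    .stopf("variable '%s': some universe points have no positive membership", name)
  }
  core_mid <- vapply(v$terms, function(mf) {
    bp <- mf$breakpoints
    if (mf$shape == "triangular") mean(bp[2]) else mean(bp[2:3])
  }, numeric(1))
  if (is.unsorted(core_mid, strictly = TRUE)) {
    .stopf("variable '%s': term cores must be ordered Low < Medium < High", name)
  }
  v
}

#' Fuzzify an indicator value
#'
#' Values outside the variable's universe are clamped to its bounds.
#'
#' @param x indicator value(s).
#' @param var a [fuzzy_variable()].
#' @return for scalar `x`, a named degree vector over `Low`, `Medium`, `High`;
#'   for vector `x`, a matrix with one row per value.
#' @export
fuzzify <- function(x, var) {
  stopifnot(inherits(var, "fuzzy_variable"))
  x <- pmin(pmax(x, var$universe[1]), var$universe[2])
  deg <- vapply(var$terms, mf_eval, numeric(length(x)), x = x)
  if (length(x) == 1L) setNames(as.numeric(deg), .levels) else deg
}

#' Rule base over the three indicator terms
#'
#' A complete 27-entry table mapping every `(perclos, ecd, aot)` term
#' combination to an output term. Validated for totality and monotonicity
#' (raising any antecedent term never lowers the output term).
#'
#' @param rules data.frame with columns `perclos`, `ecd`, `aot`, `output`,
#'   each entry one of `Low`, `Medium`, `High`.
#' @return object of class `rule_base`.
#' @export
rule_base <- function(rules) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  need <- c(.fis_vars, "output")
  if (!all(need %in% names(rules))) {
    .stopf("rule base needs columns %s", paste(need, collapse = ", "))
  }
  for (col in need) {
    bad <- !rules[[col]] %in% .levels
    if (any(bad)) .stopf("rule %d: invalid term '%s' in %s",
                         which(bad)[1], rules[[col]][which(bad)[1]], col)
  }
  key <- do.call(paste, c(rules[.fis_vars], sep = "|"))
  if (anyDuplicated(key)) .stopf("duplicate rule for antecedent (%s)", key[duplicated(key)][1])
  full <- expand.grid(perclos = .levels, ecd = .levels, aot = .levels,
                      stringsAsFactors = FALSE)
  fkey <- do.call(paste, c(full, sep = "|"))
  missing <- setdiff(fkey, key)
  if (length(missing)) {
    .stopf("incomplete rule base: no rule for antecedent (%s)",
           gsub("\\|", ", ", missing[1]))
  }
  ord <- function(x) match(x, .levels)
  o <- ord(rules$output)
  P <- ord(rules$perclos); E <- ord(rules$ecd); A <- ord(rules$aot)
  for (i in seq_len(nrow(rules))) {
    dominates <- P >= P[i] & E >= E[i] & A >= A[i]
    viol <- which(dominates & o < o[i])
    if (length(viol)) {
      j <- viol[1]
      .stopf(paste0("non-monotone rule base: (%s,%s,%s)->%s but dominating ",
                    "(%s,%s,%s)->%s"),
             rules$perclos[i], rules$ecd[i], rules$aot[i], rules$output[i],
             rules$perclos[j], rules$ecd[j], rules$aot[j], rules$output[j])
    }
  }
  structure(list(rules = rules), class = "rule_base")
}

#' Look up a rule-base output for crisp antecedent terms
#'
#' @param rb a [rule_base()].
#' @param perclos,ecd,aot term names.
#' @return the output term.
#' @export
rule_lookup <- function(rb, perclos, ecd, aot) {
  r <- rb$rules
  r$output[r$perclos == perclos & r$ecd == ecd & r$aot == aot]
}

#' Default rule table
#'
#' Encodes the rule semantics of the three complementary indicators, with the
#' remaining cells completed as the smallest output consistent with
#' monotonicity:
#' * all indicators Low -> Low;
#' * two eye-state indicators (PERCLOS, ECD) at Medium -> Medium;
#' * a single eye-state indicator at High (others Low) -> Medium;
#' * AOT High combined with any other indicator at Medium -> Medium;
#' * AOT High alone -> Low (guards against mouth-only false positives from
#'   conversation or singing);
#' * High requires both eye indicators High, or one eye indicator High plus
#'   the other Medium with AOT High.
#'
#' @return a [rule_base()] with 27 rules.
#' @export
default_rule_base <- function() {
  tab <- c(
    # P     E     A      out
    "Low",    "Low",    "Low",    "Low",
    "Medium", "Low",    "Low",    "Low",
    "Low",    "Medium", "Low",    "Low",
    "Medium", "Medium", "Low",    "Medium",
    "High",   "Low",    "Low",    "Medium",
    "Low",    "High",   "Low",    "Medium",
    "High",   "Medium", "Low",    "Medium",
    "Medium", "High",   "Low",    "Medium",
    "High",   "High",   "Low",    "High",
    "Low",    "Low",    "Medium", "Low",
    "Medium", "Low",    "Medium", "Low",
    "Low",    "Medium", "Medium", "Low",
    "Medium", "Medium", "Medium", "Medium",
    "High",   "Low",    "Medium", "Medium",
    "Low",    "High",   "Medium", "Medium",
    "High",   "Medium", "Medium", "Medium",
    "Medium", "High",   "Medium", "Medium",
    "High",   "High",   "Medium", "High",
    "Low",    "Low",    "High",   "Low",
    "Medium", "Low",    "High",   "Medium",
    "Low",    "Medium", "High",   "Medium",
    "Medium", "Medium", "High",   "Medium",
    "High",   "Low",    "High",   "Medium",
    "Low",    "High",   "High",   "Medium",
    "High",   "Medium", "High",   "High",
    "Medium", "High",   "High",   "High",
    "High",   "High",   "High",   "High"
  )
  m <- matrix(tab, ncol = 4, byrow = TRUE)
  rule_base(data.frame(perclos = m[, 1], ecd = m[, 2], aot = m[, 3],
                       output = m[, 4], stringsAsFactors = FALSE))
}

#' Fuzzy inference system configuration
#'
#' @param variables named list of the three [fuzzy_variable()]s.
#' @param rules a [rule_base()].
#' @param singletons named numeric output singletons, strictly increasing
#'   `Low < Medium < High`.
#' @return object of class `fis_config`.
#' @export
fis_config <- function(variables, rules, singletons = c(Low = 0, Medium = 0.5, High = 1)) {
  if (!identical(sort(names(variables)), sort(.fis_vars))) {
    .stopf("variables must be named %s", paste(.fis_vars, collapse = ", "))
  }
  for (v in .fis_vars) stopifnot(inherits(variables[[v]], "fuzzy_variable"))
  stopifnot(inherits(rules, "rule_base"))
  singletons <- singletons[.levels]
  if (anyNA(singletons) || is.unsorted(singletons, strictly = TRUE)) {
    .stopf("output singletons must be strictly increasing Low < Medium < High")
  }
  structure(list(variables = variables[.fis_vars], rule_base = rules,
                 singletons = singletons),
            class = "fis_config")
}

#' Default fuzzy inference configuration
#'
#' Trapezoidal terms with crossovers chosen against the spread of drowsiness
#' thresholds reported in the behavioural-monitoring literature (PERCLOS
#' thresholds 0.15-0.4 for one-minute-scale windows): PERCLOS Low/Medium
#' crossover at 0.15 and Medium/High at 0.30 on a `[0, 1]` universe; ECD
#' crossovers at 1 s and 4 s and AOT crossovers at 2 s and 6 s on `[0, 60]` s
#' universes. Output singletons 0, 0.5, 1 on a normalized drowsiness scale.
#' These defaults are tunable starting points, not clinically validated
#' boundaries; see [read_fis_config()] to supply your own.
#'
#' @return a [fis_config()].
#' @export
default_fis_config <- function() {
  trap <- function(...) membership_function("trapezoidal", c(...))
  vars <- list(
    perclos = fuzzy_variable("perclos", c(0, 1), list(
      Low = trap(0, 0, 0.10, 0.20),
      Medium = trap(0.10, 0.20, 0.25, 0.35),
      High = trap(0.25, 0.35, 1, 1))),
    ecd = fuzzy_variable("ecd", c(0, 60), list(
      Low = trap(0, 0, 0.5, 1.5),
      Medium = trap(0.5, 1.5, 3, 5),
      High = trap(3, 5, 60, 60))),
    aot = fuzzy_variable("aot", c(0, 60), list(
      Low = trap(0, 0, 1, 3),
      Medium = trap(1, 3, 5, 7),
      High = trap(5, 7, 60, 60)))
  )
  fis_config(vars, default_rule_base())
}

#' Evaluate the rule base on fuzzified inputs
#'
#' Each rule fires at the minimum of its three antecedent degrees (min as AND
#' and implication on singleton consequents); each output term's aggregated
#' degree is the maximum over the rules concluding that term.
#'
#' @param degrees list with named degree vectors `perclos`, `ecd`, `aot`
#'   (as returned by [fuzzify()]).
#' @param rb a [rule_base()].
#' @return named aggregated degree vector over `Low`, `Medium`, `High`.
#' @export
evaluate_rules <- function(degrees, rb) {
  r <- rb$rules
  fire <- pmin(degrees$perclos[r$perclos],
               degrees$ecd[r$ecd],
               degrees$aot[r$aot])
  agg <- setNames(numeric(3), .levels)
  for (lv in .levels) {
    sel <- r$output == lv
    if (any(sel)) agg[lv] <- max(fire[sel])
  }
  agg
}

#' Minimum-of-maximum defuzzification over singleton outputs
#'
#' Among the output terms attaining the maximal aggregated degree, selects the
#' one with the smallest singleton value.
#'
#' @param aggregated named aggregated degrees over `Low`, `Medium`, `High`.
#' @param singletons named, strictly increasing singleton values.
#' @return object of class `drowsiness_level`: list with `label` (term name),
#'   `state` (Normal/Drowsy/Severe alias), `crisp` (the singleton value) and
#'   `memberships` (the aggregated degree vector).
#' @export
defuzzify_min_of_max <- function(aggregated, singletons = c(Low = 0, Medium = 0.5, High = 1)) {
  aggregated <- aggregated[.levels]
  m <- max(aggregated)
  if (!is.finite(m) || m <= 0) {
    .stopf("no rule fired: all aggregated degrees are zero")
  }
  cand <- .levels[aggregated >= m - 1e-12]
  label <- cand[which.min(singletons[cand])]
  structure(list(label = label,
                 state = unname(.state_names[label]),
                 crisp = unname(singletons[label]),
                 memberships = aggregated),
            class = "drowsiness_level")
}

#' @export
print.drowsiness_level <- function(x, ...) {
  cat(sprintf("<drowsiness_level> %s (%s), crisp = %g\n", x$label, x$state, x$crisp))
  cat(sprintf("  memberships: Low %.3f | Medium %.3f | High %.3f\n",
              x$memberships["Low"], x$memberships["Medium"], x$memberships["High"]))
  invisible(x)
}

#' Infer the drowsiness level from one indicator triple
#'
#' Composition fuzzify -> rule evaluation -> min-of-max defuzzification.
#' Deterministic; out-of-universe inputs are clamped.
#'
#' @param perclos,ecd,aot finite indicator values.
#' @param cfg a [fis_config()] (default [default_fis_config()]).
#' @return a `drowsiness_level` (see [defuzzify_min_of_max()]).
#' @export
infer <- function(perclos, ecd, aot, cfg = default_fis_config()) {
  stopifnot(inherits(cfg, "fis_config"))
  if (!all(is.finite(c(perclos, ecd, aot)))) .stopf("indicator values must be finite")
  degrees <- list(perclos = fuzzify(perclos, cfg$variables$perclos),
                  ecd = fuzzify(ecd, cfg$variables$ecd),
                  aot = fuzzify(aot, cfg$variables$aot))
  defuzzify_min_of_max(evaluate_rules(degrees, cfg$rule_base), cfg$singletons)
}

#' Infer drowsiness levels for an indicator series
#'
#' Vectorized, stateless-per-sample [infer()] over the rows of an indicator
#' series (no hysteresis).
#'
#' @param indicators data.frame with columns `t`, `perclos`, `ecd`, `aot`
#'   (e.g. from [sliding_indicators()]).
#' @param cfg a [fis_config()].
#' @return data.frame of class `level_series` with columns `t`, `label`,
#'   `crisp`, `deg_low`, `deg_medium`, `deg_high`.
#' @export
infer_series <- function(indicators, cfg = default_fis_config()) {
  stopifnot(inherits(cfg, "fis_config"))
  n <- nrow(indicators)
  deg <- list(perclos = fuzzify(indicators$perclos, cfg$variables$perclos),
              ecd = fuzzify(indicators$ecd, cfg$variables$ecd),
              aot = fuzzify(indicators$aot, cfg$variables$aot))
  if (n == 1L) deg <- lapply(deg, function(d) matrix(d, 1, dimnames = list(NULL, .levels)))
  r <- cfg$rule_base$rules
  agg <- matrix(0, n, 3, dimnames = list(NULL, .levels))
  for (i in seq_len(nrow(r))) {
    fire <- pmin(deg$perclos[, r$perclos[i]], deg$ecd[, r$ecd[i]], deg$aot[, r$aot[i]])
    agg[, r$output[i]] <- pmax(agg[, r$output[i]], fire)
  }
  m <- apply(agg, 1, max)
  label <- rep(NA_character_, n)
  for (lv in .levels) {  # increasing singleton order: first hit = min-of-max
    hit <- is.na(label) & agg[, lv] >= m - 1e-12
    label[hit] <- lv
  }
  out <- data.frame(t = indicators$t, label = label,
                    crisp = unname(cfg$singletons[label]),
                    deg_low = agg[, "Low"], deg_medium = agg[, "Medium"],
                    deg_high = agg[, "High"])
  class(out) <- c("level_series", "data.frame")
  out
}

#' Write / read a fuzzy inference configuration
#'
#' The configuration is serialized as human-readable YAML (variables with
#' universes and term breakpoints, the 27-rule table, output singletons) and
#' fully re-validated at load: totality and monotonicity of the rule base,
#' ordered singletons, ordered term cores, universe coverage.
#'
#' @param cfg a [fis_config()].
#' @param path file path.
#' @return `write_fis_config`: `path` invisibly; `read_fis_config` /
#'   `load_fis_config`: the validated `fis_config`.
#' @export
write_fis_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fis_config"))
  y <- list(
    variables = lapply(cfg$variables, function(v) {
      list(universe = as.list(v$universe),
           terms = lapply(v$terms, function(mf) {
             list(shape = mf$shape, breakpoints = as.list(mf$breakpoints))
           }))
    }),
    rules = lapply(seq_len(nrow(cfg$rule_base$rules)), function(i) {
      as.list(cfg$rule_base$rules[i, , drop = FALSE])
    }),
    singletons = as.list(cfg$singletons)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_fis_config
#' @export
read_fis_config <- function(path) {
  if (!file.exists(path)) .stopf("FIS config not found: %s", path)
  y <- yaml::read_yaml(path)
  vars <- lapply(.fis_vars, function(vn) {
    v <- y$variables[[vn]]
    if (is.null(v)) .stopf("config missing variable '%s'", vn)
    terms <- lapply(v$terms, function(tm) {
      membership_function(tm$shape, unlist(tm$breakpoints))
    })
    fuzzy_variable(vn, unlist(v$universe), terms)
  })
  names(vars) <- .fis_vars
  rules <- do.call(rbind, lapply(y$rules, function(r) {
    data.frame(perclos = r$perclos, ecd = r$ecd, aot = r$aot,
               output = r$output, stringsAsFactors = FALSE)
  }))
  fis_config(vars, rule_base(rules), unlist(y$singletons))
}

#' @rdname write_fis_config
#' @export
load_fis_config <- read_fis_config

#' @export
print.fis_config <- function(x, ...) {
  cat("<fis_config> Mamdani, min/max operators, singleton outputs, min-of-max defuzzification\n")
  for (v in x$variables) {
    cat(sprintf("  %s: universe [%g, %g]\n", v$name, v$universe[1], v$universe[2]))
  }
  counts <- table(factor(x$rule_base$rules$output, levels = .levels))
  cat(sprintf("  rules: 27 (outputs: %d Low, %d Medium, %d High)\n",
              counts["Low"], counts["Medium"], counts["High"]))
  cat(sprintf("  singletons: Low %g, Medium %g, High %g\n",
              x$singletons["Low"], x$singletons["Medium"], x$singletons["High"]))
  invisible(x)
}
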