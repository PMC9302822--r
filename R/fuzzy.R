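# Mamdani fuzzy inference engine for mechanoregulated tissue differentiation.
#
# Seven input state variables (two strain invariants, in percent, plus five
# biological concentrations in percent) are mapped through 19 linguistic
# if-then rules to daily changes in blood perfusion, woven-bone and cartilage
# concentration.  Inference is classical Mamdani: min AND, 1 - mu negation,
# clipping implication, max aggregation, centroid defuzzification on a uniform
# discretization of the output universe.

#' Trapezoidal membership function
#'
#' Constructs a trapezoidal fuzzy membership function with breakpoints
#' `a <= b <= c <= d`: membership is 0 below `a`, ramps linearly to 1 on
#' `[a, b]`, is 1 on `[b, c]`, ramps down to 0 on `[c, d]` and is 0 above
#' `d`.  Infinite `a`/`d` produce open shoulders (membership stays 1 towards
#' that side); degenerate ramps (`a == b` or `c == d`) evaluate as step
#' edges.
#'
#' @param a,b,c,d Numeric breakpoints, non-decreasing; `a`, `d` may be
#'   `-Inf` / `Inf`.
#' @return An object of class `trapmf`.
#' @examples
#' mf <- trapmf(0, 2, 10, 15)
#' fuzzify(c(1, 6, 20), mf)
#' @export
trapmf <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (length(v) != 4L || anyNA(v)) {
    stop("trapmf breakpoints must be four non-missing numbers")
  }
  if (is.unsorted(v)) {
    stop(sprintf("trapmf breakpoints must be non-decreasing, got (%s)",
                 paste(signif(v, 6), collapse = ", ")))
  }
  structure(list(a = a, b = b, c = c, d = d), class = "trapmf")
}

#' @export
print.trapmf <- function(x, ...) {
  cat(sprintf("trapezoidal membership function (%g, %g, %g, %g)\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Evaluate a membership function
#'
#' @param x Numeric vector of crisp values.
#' @param mf A [trapmf()] membership function.
#' @return Membership degrees in `[0, 1]`, same length as `x`.
#' @export
fuzzify <- function(x, mf) {
  if (!inherits(mf, "trapmf")) stop("`mf` must be a trapmf object")
  a <- mf$a; b <- mf$b; cc <- mf$c; d <- mf$d
  mu <- numeric(length(x))
  mu[x >= b & x <= cc] <- 1
  lo <- which(x < b)
  if (length(lo)) {
    mu[lo] <- if (!is.finite(a)) 1 else if (a == b) 0 else pmax(0, (x[lo] - a) / (b - a))
  }
  hi <- which(x > cc)
  if (length(hi)) {
    mu[hi] <- if (!is.finite(d)) 1 else if (cc == d) 0 else pmax(0, (d - x[hi]) / (d - cc))
  }
  mu
}

#' Fuzzy linguistic variable
#'
#' Bundles a variable name, its universe of discourse and a named list of
#' trapezoidal terms.  Construction validates that the terms cover the
#' universe: on a fine sample of the universe no two consecutive points may
#' both have zero membership in every term (isolated boundary zeros, e.g.
#' where two adjacent terms meet exactly, are permitted).
#'
#' @param name Variable name.
#' @param universe Length-2 numeric, `c(min, max)`.
#' @param terms Named list of [trapmf()] objects.
#' @return An object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, universe, terms) {
  stopifnot(is.character(name), length(universe) == 2L, universe[1] < universe[2])
  if (!length(terms) || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("`terms` must be a non-empty named list of trapmf objects")
  }
  for (tm in terms) {
    if (!inherits(tm, "trapmf")) stop("every term must be a trapmf object")
  }
  xs <- seq(universe[1], universe[2], length.out = 257L)
  cover <- Reduce(`+`, lapply(terms, function(mf) fuzzify(xs, mf) > 0))
  gap <- which(cover == 0)
  if (any(diff(gap) == 1L)) {
    stop(sprintf("terms of '%s' leave an uncovered gap of positive width near %g",
                 name, xs[gap[which(diff(gap) == 1L)[1]]]))
  }
  structure(list(name = name, universe = as.numeric(universe), terms = terms),
            class = "fuzzy_variable")
}

#' Default fuzzy variables of the healing controller
#'
#' Returns the seven input and three output linguistic variables.  Strain
#' inputs are in percent strain (`eps_hyd` signed, `eps_dis` non-negative),
#' concentrations and perfusion in percent, outputs in percent per day on the
#' universe `[-10, 10]`.  The trapezoid breakpoints follow the
#' Claes-Heigele-type mechanoregulation thresholds: distortional strain is
#' callus-friendly roughly between 2% and 10% and destructive beyond ~15%;
#' hydrostatic strain bands are compression-biased, with the osteogenic
#' "low" bands reaching down to a disuse threshold of 0.005-0.02%
#' hydrostatic strain (mechanostat-type cutoff, roughly 400-1500
#' microstrain axial) so that well-perfused periosteal surfaces at
#' physiological strain remain osteogenic while truly unloaded tissue is
#' quiescent.  All breakpoints are calibration parameters and can be
#' overridden through the `[fuzzy]` config section (see
#' [default_config()]); the methods vignette discusses their sensitivity.
#'
#' @return Named list of [fuzzy_variable()] objects.
#' @export
default_fuzzy_variables <- function() {
  conc_terms <- list(
    "low"    = trapmf(-Inf, 0, 10, 30),
    "medium" = trapmf(10, 30, 70, 90),
    "high"   = trapmf(70, 90, 100, Inf)
  )
  out_terms <- list(
    "decrease" = trapmf(-10, -10, -5, 0),
    "increase" = trapmf(0, 5, 10, 10)
  )
  vars <- list(
    fuzzy_variable("eps_hyd", c(-10, 10), list(
      "neg destructive" = trapmf(-Inf, -Inf, -8, -5),
      "neg medium"      = trapmf(-8, -5, -2, -1),
      "neg low"         = trapmf(-2, -1, -0.02, -0.005),
      "about zero"      = trapmf(-0.02, -0.005, 0.005, 0.02),
      "pos low"         = trapmf(0.005, 0.02, 2, 5),
      "pos destructive" = trapmf(4, 8, Inf, Inf)
    )),
    fuzzy_variable("eps_dis", c(0, 30), list(
      "zero"        = trapmf(-Inf, 0, 1, 2),
      "low"         = trapmf(1, 2, 10, 12),
      "destructive" = trapmf(10, 15, Inf, Inf)
    )),
    fuzzy_variable("c_perfusion", c(0, 100), conc_terms),
    fuzzy_variable("c_perfusion_neighbour", c(0, 100), conc_terms),
    fuzzy_variable("c_bone", c(0, 100), conc_terms),
    fuzzy_variable("c_bone_neighbour", c(0, 100), conc_terms),
    fuzzy_variable("c_cartilage", c(0, 100), conc_terms),
    fuzzy_variable("d_perfusion", c(-10, 10), out_terms),
    fuzzy_variable("d_bone", c(-10, 10), out_terms),
    fuzzy_variable("d_cartilage", c(-10, 10), out_terms)
  )
  names(vars) <- vapply(vars, `[[`, "", "name")
  vars
}

#' Names of the controller input and output variables
#' @keywords internal
fuzzy_input_names <- function() {
  c("eps_hyd", "eps_dis", "c_perfusion", "c_perfusion_neighbour",
    "c_bone", "c_bone_neighbour", "c_cartilage")
}

#' @rdname fuzzy_input_names
#' @keywords internal
fuzzy_output_names <- function() c("d_perfusion", "d_bone", "d_cartilage")

# Normalize a linguistic term as printed in the rule table to a canonical
# term key, returning list(term=, negated=).  "-" means "variable absent".
normalize_term <- function(txt, variable) {
  raw <- tolower(trimws(txt))
  if (raw %in% c("-", "")) return(NULL)
  raw <- gsub("\\.", " ", raw)
  raw <- gsub("\\s+", " ", trimws(raw))
  negated <- FALSE
  if (startsWith(raw, "not ")) {
    negated <- TRUE
    raw <- trimws(sub("^not ", "", raw))
  }
  if (variable == "eps_dis" && raw == "about zero") raw <- "zero"
  list(term = raw, negated = negated)
}

#' Load the tissue-differentiation rule base
#'
#' Reads the 19 linguistic rules describing angiogenesis, intramembranous
#' ossification, chondrogenesis, cartilage calcification, endochondral
#' ossification and tissue destruction from a tab-separated table (one row
#' per rule, columns: `Rule`, the seven input variables, the three output
#' deltas and `Process`).  A `-` entry means the variable does not appear in
#' the rule; a `Not` prefix negates the term.  The canonical table ships
#' with the package.
#'
#' @param path Path to a rules TSV.  `NULL` (default) loads the shipped
#'   canonical table.
#' @param variables Fuzzy variables used to validate term names.
#' @param strict If `TRUE` (default), require exactly 19 rules and validate
#'   output terms against `increase`/`decrease`.
#' @return An object of class `fuzzy_rulebase`: list of rules, each with
#'   `antecedents` (data.frame `variable`, `term`, `negated`), `consequents`
#'   (data.frame `variable`, `term`) and a `process` label.
#' @export
load_rulebase <- function(path = NULL, variables = default_fuzzy_variables(),
                          strict = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_rules.tsv", package = "callusim",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("rules file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  col_map <- c(
    "eps_hyd" = "eps_hyd", "eps_dis" = "eps_dis",
    "C_perfusion" = "c_perfusion",
    "C_perfusion_neighbour" = "c_perfusion_neighbour",
    "C_bone" = "c_bone", "C_bone_neighbour" = "c_bone_neighbour",
    "C_cartilage" = "c_cartilage",
    "d_perfusion" = "d_perfusion", "d_bone" = "d_bone",
    "d_cartilage" = "d_cartilage"
  )
  missing_cols <- setdiff(c("Rule", names(col_map), "Process"), names(tab))
  if (length(missing_cols)) {
    stop("rules file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (strict && nrow(tab) != 19L) {
    stop(sprintf("rule base must contain exactly 19 rules, found %d", nrow(tab)))
  }
  in_names <- fuzzy_input_names()
  out_names <- fuzzy_output_names()
  rules <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    ants <- list()
    cons <- list()
    for (col in names(col_map)) {
      var <- col_map[[col]]
      parsed <- normalize_term(tab[[col]][r], var)
      if (is.null(parsed)) next
      if (var %in% in_names) {
        if (!parsed$term %in% names(variables[[var]]$terms)) {
          stop(sprintf("rule %s: unknown term '%s' for input variable '%s'",
                       tab$Rule[r], parsed$term, var))
        }
        ants[[length(ants) + 1L]] <- data.frame(
          variable = var, term = parsed$term, negated = parsed$negated,
          stringsAsFactors = FALSE)
      } else {
        if (strict && !parsed$term %in% c("increase", "decrease")) {
          stop(sprintf("rule %s: output term must be Increase or Decrease, got '%s'",
                       tab$Rule[r], tab[[col]][r]))
        }
        if (!parsed$term %in% names(variables[[var]]$terms)) {
          stop(sprintf("rule %s: unknown term '%s' for output variable '%s'",
                       tab$Rule[r], parsed$term, var))
        }
        if (parsed$negated) {
          stop(sprintf("rule %s: negated consequents are not allowed", tab$Rule[r]))
        }
        cons[[length(cons) + 1L]] <- data.frame(
          variable = var, term = parsed$term, stringsAsFactors = FALSE)
      }
    }
    if (!length(cons)) {
      stop(sprintf("rule %s has no consequent", tab$Rule[r]))
    }
    rules[[r]] <- list(
      antecedents = if (length(ants)) do.call(rbind, ants) else
        data.frame(variable = character(), term = character(),
                   negated = logical(), stringsAsFactors = FALSE),
      consequents = do.call(rbind, cons),
      process = trimws(tab$Process[r])
    )
  }
  structure(list(rules = rules, source = path), class = "fuzzy_rulebase")
}

#' @export
print.fuzzy_rulebase <- function(x, ...) {
  cat(sprintf("fuzzy rule base: %d rules\n", length(x$rules)))
  print(table(vapply(x$rules, `[[`, "", "process")))
  invisible(x)
}

#' Activation degree of a single rule
#'
#' Computes the Mamdani activation of one rule: the minimum over its
#' antecedents of the (possibly negated) term membership of the
#' corresponding input value.  A rule with no antecedents activates at 1.
#'
#' @param inputs Named numeric vector with the seven controller inputs
#'   (see [fuzzy_input_names()]); values are clamped to each variable's
#'   universe.
#' @param rule A single rule from a [load_rulebase()] object.
#' @param variables Fuzzy variable list.
#' @return Activation degree in `[0, 1]`.
#' @export
rule_activation <- function(inputs, rule, variables = default_fuzzy_variables()) {
  act <- 1
  ants <- rule$antecedents
  for (k in seq_len(nrow(ants))) {
    var <- ants$variable[k]
    u <- variables[[var]]$universe
    x <- min(max(inputs[[var]], u[1]), u[2])
    mu <- fuzzify(x, variables[[var]]$terms[[ants$term[k]]])
    if (ants$negated[k]) mu <- 1 - mu
    act <- min(act, mu)
  }
  act
}

#' Assemble a fuzzy controller
#'
#' Validates a rule base against a variable set and precomputes the output
#' discretization grids used for centroid defuzzification.
#'
#' @param variables Fuzzy variables, see [default_fuzzy_variables()].
#' @param rulebase Rule base, see [load_rulebase()].
#' @param n_grid Number of points of the uniform output discretization used
#'   by the centroid method (default 1001).
#' @return An object of class `fuzzy_controller`.
#' @export
fuzzy_controller <- function(variables = default_fuzzy_variables(),
                             rulebase = load_rulebase(variables = variables),
                             n_grid = 1001L) {
  stopifnot(inherits(rulebase, "fuzzy_rulebase"), n_grid >= 11L)
  for (r in seq_along(rulebase$rules)) {
    rule <- rulebase$rules[[r]]
    for (k in seq_len(nrow(rule$antecedents))) {
      var <- rule$antecedents$variable[k]
      tm <- rule$antecedents$term[k]
      if (is.null(variables[[var]]) || !tm %in% names(variables[[var]]$terms)) {
        stop(sprintf("rule %d references unknown term '%s' of variable '%s'", r, tm, var))
      }
    }
  }
  outputs <- lapply(fuzzy_output_names(), function(ov) {
    var <- variables[[ov]]
    y <- seq(var$universe[1], var$universe[2], length.out = n_grid)
    mu <- vapply(var$terms, function(mf) fuzzify(y, mf), numeric(n_grid))
    # rules feeding each term of this output variable
    feeders <- lapply(names(var$terms), function(tm) {
      which(vapply(rulebase$rules, function(rule) {
        any(rule$consequents$variable == ov & rule$consequents$term == tm)
      }, logical(1)))
    })
    names(feeders) <- names(var$terms)
    list(name = ov, grid = y, term_mu = mu, feeders = feeders)
  })
  names(outputs) <- fuzzy_output_names()
  structure(list(variables = variables, rulebase = rulebase,
                 n_grid = as.integer(n_grid), outputs = outputs),
            class = "fuzzy_controller")
}

# Activation of every rule for a matrix of inputs (rows = cases).
rule_activation_matrix <- function(X, controller) {
  vars <- controller$variables
  rules <- controller$rulebase$rules
  n <- nrow(X)
  A <- matrix(1, n, length(rules))
  for (r in seq_along(rules)) {
    ants <- rules[[r]]$antecedents
    act <- rep(1, n)
    for (k in seq_len(nrow(ants))) {
      var <- ants$variable[k]
      u <- vars[[var]]$universe
      x <- pmin(pmax(X[, var], u[1]), u[2])
      mu <- fuzzify(x, vars[[var]]$terms[[ants$term[k]]])
      if (ants$negated[k]) mu <- 1 - mu
      act <- pmin(act, mu)
    }
    A[, r] <- act
  }
  A
}

# Centroid of the aggregated (max of clipped term shapes) output on the
# discretized universe, vectorized over cases; zero where nothing fires.
defuzzify_centroid <- function(term_activation, out_spec, chunk = NULL) {
  y <- out_spec$grid
  G <- length(y)
  if (is.null(chunk)) chunk <- max(16L, as.integer(4e6 %/% G))
  terms <- colnames(out_spec$term_mu)
  n <- nrow(term_activation)
  res <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    m <- length(idx)
    agg <- matrix(0, m, G)
    for (tm in terms) {
      a <- term_activation[idx, tm]
      if (!any(a > 0)) next
      clip <- pmin(matrix(a, m, G), matrix(out_spec$term_mu[, tm], m, G, byrow = TRUE))
      agg <- pmax(agg, clip)
    }
    den <- rowSums(agg)
    num <- as.numeric(agg %*% y)
    res[idx] <- ifelse(den > 1e-300, num / den, 0)
  }
  res
}

#' Fuzzy inference for a batch of elements
#'
#' Runs the full Mamdani pipeline (fuzzification, min-AND rule activation,
#' clipping, max aggregation, centroid defuzzification) for every row of an
#' input matrix.
#'
#' @param X Numeric matrix with one row per case and the seven input columns
#'   named as in [fuzzy_input_names()]; values are clamped to the variable
#'   universes.
#' @param controller A [fuzzy_controller()].
#' @return Matrix with columns `d_perfusion`, `d_bone`, `d_cartilage`
#'   (percent per day).  Outputs are 0 where no rule fires.
#' @export
infer_bulk <- function(X, controller) {
  if (!inherits(controller, "fuzzy_controller")) {
    stop("`controller` must be a fuzzy_controller object")
  }
  X <- as.matrix(X)
  miss <- setdiff(fuzzy_input_names(), colnames(X))
  if (length(miss)) stop("input matrix lacks columns: ", paste(miss, collapse = ", "))
  A <- rule_activation_matrix(X, controller)
  out <- matrix(0, nrow(X), 3L, dimnames = list(NULL, fuzzy_output_names()))
  for (ov in fuzzy_output_names()) {
    spec <- controller$outputs[[ov]]
    term_act <- vapply(names(spec$feeders), function(tm) {
      rs <- spec$feeders[[tm]]
      if (!length(rs)) return(numeric(nrow(X)))
      if (length(rs) == 1L) A[, rs] else do.call(pmax, lapply(rs, function(r) A[, r]))
    }, numeric(nrow(X)))
    if (nrow(X) == 1L) term_act <- matrix(term_act, 1L, dimnames = list(NULL, names(spec$feeders)))
    out[, ov] <- defuzzify_centroid(term_act, spec)
  }
  out
}

#' Fuzzy inference for a single input vector
#'
#' @param inputs Named numeric vector with the seven controller inputs.
#' @param controller A [fuzzy_controller()].
#' @return Named numeric vector `(d_perfusion, d_bone, d_cartilage)` in
#'   percent per day.
#' @export
infer <- function(inputs, controller) {
  x <- matrix(unlist(inputs[fuzzy_input_names()]), nrow = 1,
              dimnames = list(NULL, fuzzy_input_names()))
  drop(infer_bulk(x, controller))
}
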