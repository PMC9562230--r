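# Dimensionless Pi-forms over a modulator's variables.
#
# A Pi-form is a ratio of two branches. A branch is either a sum of distinct
# plain variables (each term degree 1) or a monomial with positive integer
# exponents. Dimensional homogeneity requires the degree of every additive
# term in the numerator to equal the total degree of the denominator, which
# makes the form invariant under a common rescaling of all variables (all
# variables within a modulator share one unit, e.g. micrograms per litre).

new_branch_sum <- function(vars) {
  vars <- sort(unique(as.integer(vars)))
  if (length(vars) < 2L) {
    abort("A sum branch needs at least two distinct variables.",
          class = "winepi_error_form")
  }
  list(kind = "sum", vars = vars)
}

new_branch_mono <- function(powers) {
  powers <- powers[powers != 0]
  if (length(powers) == 0L || any(powers < 0) || any(powers != floor(powers))) {
    abort("A monomial branch needs positive integer exponents.",
          class = "winepi_error_form")
  }
  idx <- as.integer(names(powers))
  o <- order(idx)
  list(kind = "mono", vars = idx[o], powers = as.integer(powers[o]))
}

branch_degree <- function(branch) {
  switch(branch$kind,
         sum  = 1L,                       # every term is a single plain variable
         mono = sum(branch$powers))
}

format_branch <- function(branch, wrap = FALSE) {
  txt <- switch(branch$kind,
    sum  = paste0("(", paste0("x", branch$vars, collapse = "+"), ")"),
    mono = {
      t <- ifelse(branch$powers == 1L,
                  paste0("x", branch$vars),
                  paste0("x", branch$vars, "^", branch$powers))
      s <- paste0(t, collapse = "*")
      if (wrap && length(t) > 1L) paste0("(", s, ")") else s
    })
  txt
}

#' Construct a Pi-form
#'
#' Builds a dimensionless candidate expression `numerator / denominator` over
#' the indexed variables `x1, x2, ...` of a flavour modulator. Branches are
#' given in the compact text notation also used for serialisation, e.g.
#' `"(x1+x2)/x3"`, `"x1*x3/x2^2"`, `"x3/(x1+x2)"`.
#'
#' Construction does not enforce homogeneity (so that malformed candidates can
#' be represented and rejected); use [check_homogeneity()] to validate and
#' [evaluate_pi()] to evaluate, which refuses non-homogeneous forms.
#'
#' @param text A single string in the compact notation.
#' @return An object of class `pi_form` with fields `id`, `num`, `den`.
#' @examples
#' f <- pi_form("(x1+x2)/x3")
#' check_homogeneity(f)
#' evaluate_pi(f, c(2, 4, 3))
#' @export
pi_form <- function(text) {
  parse_pi_form(text)
}

new_pi_form <- function(num, den) {
  # numerator binds tighter than the division in the compact notation
  # ("x1*x3/x2^2"); multi-term denominators are parenthesised ("x1^2/(x2*x3)")
  id <- paste0(format_branch(num, wrap = FALSE), "/", format_branch(den, wrap = TRUE))
  structure(list(id = id, num = num, den = den), class = "pi_form")
}

parse_branch <- function(txt) {
  txt <- gsub("\\s+", "", txt)
  inner <- sub("^\\((.*)\\)$", "\\1", txt)
  if (grepl("+", inner, fixed = TRUE)) {
    parts <- strsplit(inner, "+", fixed = TRUE)[[1]]
    ok <- grepl("^x[0-9]+$", parts)
    if (!all(ok)) {
      abort(sprintf("Cannot parse sum branch '%s': terms must be plain variables.", txt),
            class = "winepi_error_form")
    }
    return(new_branch_sum(as.integer(sub("^x", "", parts))))
  }
  parts <- strsplit(inner, "*", fixed = TRUE)[[1]]
  powers <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^x([0-9]+)(\\^([0-9]+))?$", p))[[1]]
    if (length(m) == 0L) {
      abort(sprintf("Cannot parse monomial term '%s'.", p), class = "winepi_error_form")
    }
    v <- m[2]
    e <- if (m[4] == "") 1L else as.integer(m[4])
    powers[v] <- (if (v %in% names(powers)) powers[[v]] else 0L) + e
  }
  new_branch_mono(powers)
}

#' Parse a Pi-form from its text notation
#'
#' @param text e.g. `"(x1+x2)/x3"` or `"x2^2/(x1*x3)"`.
#' @return A `pi_form`.
#' @export
parse_pi_form <- function(text) {
  if (inherits(text, "pi_form")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("\\s+", "", text)
  # split on the "/" at parenthesis depth zero
  depth <- 0L; cut <- NA_integer_
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "/" && depth == 0L) { cut <- i; break }
  }
  if (is.na(cut)) {
    abort(sprintf("Pi-form '%s' must be a ratio 'numerator/denominator'.", text),
          class = "winepi_error_form")
  }
  new_pi_form(parse_branch(substr(txt, 1L, cut - 1L)),
              parse_branch(substr(txt, cut + 1L, nchar(txt))))
}

#' @export
format.pi_form <- function(x, ...) x$id

#' @export
print.pi_form <- function(x, ...) {
  cat("<pi_form> ", x$id,
      if (check_homogeneity(x)) "" else "  [not dimensionally homogeneous]",
      "\n", sep = "")
  invisible(x)
}

form_vars <- function(form) sort(unique(c(form$num$vars, form$den$vars)))

#' Check dimensional homogeneity of a Pi-form
#'
#' A form is dimensionally homogeneous (hence dimensionless) when the unit
#' degree of every additive term in the numerator equals the total degree of
#' the denominator. For example `(x1+x2)/x3` balances at degree 1/1 and
#' `x1*x3/x2^2` at 2/2, while `x1*x3/x2` carries a net unit and is rejected.
#'
#' @param form A `pi_form` or its text notation.
#' @return `TRUE` iff the net unit degree is zero for every additive branch.
#' @export
check_homogeneity <- function(form) {
  form <- parse_pi_form(form)
  branch_degree(form$num) == branch_degree(form$den)
}

eval_branch <- function(branch, values) {
  # `values` is a numeric matrix (rows = observations, cols = variables)
  switch(branch$kind,
    sum  = rowSums(values[, branch$vars, drop = FALSE]),
    mono = {
      out <- rep(1, nrow(values))
      for (j in seq_along(branch$vars)) {
        out <- out * values[, branch$vars[j]]^branch$powers[j]
      }
      out
    })
}

as_value_matrix <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  storage.mode(values) <- "double"
  values
}

#' Evaluate a Pi-form on positive variable values
#'
#' @param form A `pi_form` (or text notation); must be dimensionally
#'   homogeneous.
#' @param values A positive numeric vector (one observation) or a matrix /
#'   data frame with one column per variable `x1, x2, ...` (rows are wines).
#' @return A numeric vector of evaluated Pi-term values, one per observation;
#'   always finite and strictly positive.
#' @export
evaluate_pi <- function(form, values) {
  form <- parse_pi_form(form)
  if (!check_homogeneity(form)) {
    abort(sprintf("Pi-form '%s' is not dimensionally homogeneous.", form$id),
          class = "winepi_error_form")
  }
  m <- as_value_matrix(values)
  need <- max(form_vars(form))
  if (ncol(m) < need) {
    abort(sprintf("Pi-form '%s' needs %d variables; got %d.", form$id, need, ncol(m)),
          class = "winepi_error_domain")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("All variable values must be finite and strictly positive.",
          class = "winepi_error_domain")
  }
  unname(eval_branch(form$num, m) / eval_branch(form$den, m))
}

#' Evaluate several Pi-forms as a tidy table
#'
#' @param forms A list of `pi_form`s (or text notations), optionally named.
#' @param values As in [evaluate_pi()].
#' @return A tibble with columns `form_id` and `value` (and `row` when
#'   `values` has several rows).
#' @export
pi_terms <- function(forms, values) {
  forms <- map(forms, parse_pi_form)
  m <- as_value_matrix(values)
  out <- map(forms, function(f) {
    tibble(row = seq_len(nrow(m)), form_id = f$id, value = evaluate_pi(f, m))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(m) == 1L) res$row <- NULL
  res
}

# All exponent vectors over `k` variables with total degree `d` and
# per-variable exponent at most `cap`.
degree_compositions <- function(k, d, cap) {
  grid <- as.matrix(expand.grid(rep(list(0:min(d, cap)), k)))
  grid[rowSums(grid) == d, , drop = FALSE]
}

#' Enumerate candidate dimensionless Pi-forms
#'
#' Systematically lists degree-balanced forms over `k_vars` variables:
#'
#' * additive forms `(xi + xj + ...)/xl` and their reciprocals `xl/(xi + ...)`,
#'   with the sum over any subset of at least two variables and a single
#'   remaining variable as the other branch;
#' * balanced monomial ratios `x^a / x^b` with disjoint variable support and
#'   equal total degree on both sides, up to `max_degree`.
#'
#' Every returned form passes [check_homogeneity()]; ids are the canonical
#' text notation and the list is sorted by id, so enumeration order is stable.
#'
#' @param k_vars Number of variables in the modulator (default 3).
#' @param max_degree Maximum total degree of a monomial branch (default 2).
#' @param include_sums Include the additive families (default `TRUE`).
#' @return A named list of `pi_form`s (names are the ids).
#' @export
enumerate_pi_forms <- function(k_vars = 3L, max_degree = 2L, include_sums = TRUE) {
  k_vars <- check_count(k_vars, "k_vars", min = 2L)
  max_degree <- check_count(max_degree, "max_degree", min = 1L)
  forms <- list()
  add <- function(f) forms[[f$id]] <<- f

  if (include_sums) {
    idx <- seq_len(k_vars)
    for (s in seq_len(k_vars - 1L)) {
      if (s < 2L) next  # a sum needs two terms, and one variable must remain
      subs <- utils::combn(idx, s, simplify = FALSE)
      for (S in subs) {
        for (z in setdiff(idx, S)) {
          add(new_pi_form(new_branch_sum(S), new_branch_mono(setNames(1L, z))))
          add(new_pi_form(new_branch_mono(setNames(1L, z)), new_branch_sum(S)))
        }
      }
    }
  }

  for (d in seq_len(max_degree)) {
    comps <- degree_compositions(k_vars, d, max_degree)
    for (i in seq_len(nrow(comps))) {
      for (j in seq_len(nrow(comps))) {
        a <- comps[i, ]; b <- comps[j, ]
        if (any(a > 0 & b > 0)) next  # branches must not share variables
        num <- new_branch_mono(setNames(a[a > 0], which(a > 0)))
        den <- new_branch_mono(setNames(b[b > 0], which(b > 0)))
        add(new_pi_form(num, den))
      }
    }
  }

  forms <- forms[order(names(forms))]
  stopifnot(all(map_lgl(forms, check_homogeneity)))
  forms
}

# Relabel the variables of a form under a permutation (perm[i] is the new
# index of variable i). Used to verify permutation covariance.
permute_pi_form <- function(form, perm) {
  relabel <- function(branch) {
    switch(branch$kind,
      sum  = new_branch_sum(perm[branch$vars]),
      mono = new_branch_mono(setNames(branch$powers, perm[branch$vars])))
  }
  new_pi_form(relabel(form$num), relabel(form$den))
}
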