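# Odour activity values and essential-modulator assembly.

#' Odour activity value
#'
#' The odour activity value (OAV) of a volatile compound is the ratio of its
#' concentration to its odour detection threshold (ODT); OAV > 1 flags a
#' likely contributor to wine aroma. Both inputs share a unit (conventionally
#' micrograms per litre), so the ratio is dimensionless and invariant under a
#' common unit change.
#'
#' @param concentration Compound concentration(s), same unit as `odt`; >= 0.
#' @param odt Odour detection threshold(s); must be strictly positive.
#' @return `concentration / odt`, vectorised.
#' @examples
#' compute_oav(170, 25)   # 6.8
#' compute_oav(0.2, 0.05) # 4
#' @export
compute_oav <- function(concentration, odt) {
  if (!is.numeric(odt) || any(!is.finite(odt)) || any(odt <= 0)) {
    abort("`odt` must be strictly positive (invalid odour detection threshold).",
          class = "winepi_error_invalid_threshold")
  }
  if (!is.numeric(concentration) || any(!is.finite(concentration)) ||
      any(concentration < 0)) {
    abort("`concentration` must be finite and non-negative.",
          class = "winepi_error_domain")
  }
  concentration / odt
}

#' Default compound overrides for selection
#'
#' Compounds retained as modulator members on literature grounds even when
#' their OAV does not exceed 1: benzaldehyde, heptan-1-ol and phenol, plus
#' 4-ethylphenol (this package's default third member of the "other" set,
#' kept on the same literature basis as phenol).
#'
#' @return A character vector of compound names.
#' @export
default_override_compounds <- function() {
  c("benzaldehyde", "heptan-1-ol", "phenol", "4-ethylphenol")
}

#' Select aroma-contributing compounds
#'
#' A compound is selected when its OAV exceeds 1 (strictly) in at least one
#' record, or when its name is in `overrides`. Raising a concentration can
#' therefore never deselect a compound.
#'
#' @param records A data frame with columns `name`, `concentration`, `odt`
#'   (an `oav` column is used if already present). One row per compound, or
#'   several rows per compound (e.g. one per wine).
#' @param overrides Compound names always selected;
#'   default [default_override_compounds()].
#' @return A tibble with one row per distinct compound: `name`, `max_oav`,
#'   `selected`, `reason` (`"oav"`, `"override"` or `"none"`), in first
#'   appearance order.
#' @export
select_compounds <- function(records, overrides = default_override_compounds()) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) {
    abort("`records` must contain at least one compound.", class = "winepi_error_domain")
  }
  if (!"oav" %in% names(records)) {
    records$oav <- compute_oav(records$concentration, records$odt)
  }
  records |>
    mutate(name = as.character(.data$name)) |>
    group_by(name = factor(.data$name, levels = unique(.data$name))) |>
    summarise(max_oav = max(.data$oav), .groups = "drop") |>
    mutate(
      name = as.character(.data$name),
      by_oav = .data$max_oav > 1,
      by_override = .data$name %in% overrides,
      selected = .data$by_oav | .data$by_override,
      reason = dplyr::case_when(.data$by_oav ~ "oav",
                                .data$by_override ~ "override",
                                TRUE ~ "none")
    ) |>
    select("name", "max_oav", "selected", "reason")
}

#' Default chemical modulator assignment
#'
#' Maps compounds to the five essential flavour modulators: M1 fruity (ethyl
#' esters), M2 herbal (C6/C7 alcohols), M3 floral (beta-damascenone,
#' 2-phenylethan-1-ol, linalool), M4 oak/woody (eugenol, benzaldehyde,
#' guaiacol), M5 spicy/other (phenol, eugenol and a configurable third
#' phenolic volatile). Eugenol legitimately appears in both M4 and M5. Member
#' order within a set is meaningful: it fixes which variable is `x1`, `x2`,
#' `x3` in a Pi-form.
#'
#' @param m5_third Third member of M5 (default `"4-ethylphenol"`, giving 14
#'   distinct modulator variables); set `"guaiacol"` to reuse the woody
#'   phenol instead, or `NULL` to run M5 with two members only (its Pi-form
#'   then degenerates to the two-variable ratio `x1/x2`).
#' @return A tibble `modulator`, `label`, `member`, `position` — data, not
#'   code, so other varieties or studies can re-map compounds.
#' @export
default_modulator_assignment <- function(m5_third = "4-ethylphenol") {
  m5 <- c("phenol", "eugenol", m5_third)
  rows <- list(
    M1 = list(label = "fruity", members = c("ethyl octanoate", "ethyl butanoate", "ethyl hexanoate")),
    M2 = list(label = "herbal", members = c("hexan-1-ol", "(E)-hex-3-en-1-ol", "heptan-1-ol")),
    M3 = list(label = "floral", members = c("beta-damascenone", "2-phenylethan-1-ol", "linalool")),
    M4 = list(label = "woody",  members = c("eugenol", "benzaldehyde", "guaiacol")),
    M5 = list(label = "other",  members = m5)
  )
  purrr::imap(rows, function(r, nm) {
    tibble(modulator = nm, label = r$label, member = r$members,
           position = seq_along(r$members))
  }) |> dplyr::bind_rows()
}

#' Physiochemical modulator assignment (two Pi-groups)
#'
#' The case-study configuration over six physiochemical variables: group P1 =
#' total sulphur, total phenolics, titratable acidity; group P2 = sugar,
#' ethanol, pH.
#'
#' @return A tibble in the same shape as [default_modulator_assignment()].
#' @export
physiochem_modulator_assignment <- function() {
  dplyr::bind_rows(
    tibble(modulator = "P1", label = "structure",
           member = c("total_sulphur", "total_phenolics", "titratable_acidity"),
           position = 1:3),
    tibble(modulator = "P2", label = "balance",
           member = c("sugar", "ethanol", "pH"), position = 1:3)
  )
}

#' Assemble essential-modulator sets from selected compounds
#'
#' @param selected Character vector of selected compound names (e.g. the
#'   selected rows of [select_compounds()]).
#' @param assignment Compound-to-modulator map,
#'   default [default_modulator_assignment()].
#' @return An object of class `modulator_sets`: a tibble with one row per
#'   modulator (`modulator`, `label`, `members` list-column). Each set keeps
#'   its assigned member order.
#' @export
assemble_modulators <- function(selected, assignment = default_modulator_assignment()) {
  assignment <- as_tibble(assignment)
  sets <- assignment |>
    group_by(.data$modulator, .data$label) |>
    arrange(.data$position, .by_group = TRUE) |>
    summarise(members = list(.data$member),
              available = list(intersect(.data$member, selected)),
              .groups = "drop")
  expected <- map_dbl(sets$members, length)
  got <- map_dbl(sets$available, length)
  bad <- got != expected | (expected != 3L & expected != 2L)
  if (any(bad)) {
    missing <- purrr::map2(sets$members[bad], sets$available[bad], setdiff)
    abort(paste0(
      "Cannot assemble modulator set(s): ",
      paste0(sets$modulator[bad], " (missing: ",
             map_chr(missing, function(m) {
               if (length(m)) paste(m, collapse = ", ") else "needs 3 members"
             }), ")", collapse = "; ")),
      class = "winepi_error_assembly")
  }
  dup <- map_lgl(sets$members, function(m) anyDuplicated(m) > 0)
  if (any(dup)) {
    abort(paste0("Duplicated member within modulator set(s): ",
                 paste(sets$modulator[dup], collapse = ", ")),
          class = "winepi_error_assembly")
  }
  structure(sets |> select("modulator", "label", "members"),
            class = c("modulator_sets", class(sets)))
}

#' Evaluate Pi-terms per wine for a set of modulators
#'
#' Looks up each modulator's member columns in `data` (in member order, so the
#' first member is `x1`) and evaluates the chosen Pi-form per wine.
#'
#' @param data A wine table: `wine_id` column plus one numeric column per
#'   compound/variable.
#' @param modulators A `modulator_sets` object from [assemble_modulators()].
#' @param forms A single Pi-form (or text) applied to every modulator, or a
#'   named list/character vector with one form per modulator id. Two-member
#'   sets use the ratio `x1/x2` regardless.
#' @return A tibble: `wine_id` plus one positive column per modulator holding
#'   its evaluated Pi-term.
#' @export
compute_pi_terms <- function(data, modulators, forms = "(x1+x2)/x3") {
  data <- as_tibble(data)
  ids <- modulators$modulator
  if (length(forms) == 1L && is.null(names(forms))) {
    forms <- setNames(rep(list(forms[[1]]), length(ids)), ids)
  }
  if (!all(ids %in% names(forms))) {
    abort(paste0("`forms` must name every modulator: ",
                 paste(setdiff(ids, names(forms)), collapse = ", ")),
          class = "winepi_error_config")
  }
  out <- tibble(wine_id = data$wine_id)
  for (i in seq_along(ids)) {
    members <- modulators$members[[i]]
    miss <- setdiff(members, names(data))
    if (length(miss)) {
      abort(sprintf("Wine table lacks column(s) %s needed by modulator %s.",
                    paste0("'", miss, "'", collapse = ", "), ids[i]),
            class = "winepi_error_config")
    }
    f <- if (length(members) == 2L) pi_form("x1/x2") else parse_pi_form(forms[[ids[i]]])
    out[[ids[i]]] <- evaluate_pi(f, data[, members])
  }
  out
}
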