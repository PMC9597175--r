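# Model readers and writers: tabular (TSV) dialect, JSON, and an SBML Level 3
# FBC subset. The tabular dialect is the native fixture format: one reactions
# table (id, equation, lb, ub, gpr, confidence) and one metabolites table, with
# compartments encoded as a bracketed id suffix.

#' Load a constraint-based model
#'
#' @param path File path. For `format = "tsv"` this is the reactions table;
#'   the metabolites table defaults to the same path with "reactions" replaced
#'   by "metabolites" (or is derived from the equations when that file does
#'   not exist).
#' @param format `"auto"` (by extension), `"tsv"`, `"json"` or `"sbml"`.
#' @param biomass_rxn_id,atp_rxn_id Objective reaction ids. Optional for
#'   formats that embed them (JSON, SBML written by this package).
#' @param metabolites_path Optional explicit metabolites TSV path.
#' @return A [metnet_model()].
#' @export
load_model <- function(path, format = c("auto", "tsv", "json", "sbml"),
                       biomass_rxn_id = NULL, atp_rxn_id = NULL,
                       metabolites_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     "json" = "json", "xml" = "sbml", "sbml" = "sbml", "tsv")
  }
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "actd_io_error")
  }
  switch(format,
    tsv = read_model_tsv(path, metabolites_path, biomass_rxn_id, atp_rxn_id),
    json = read_model_json(path, biomass_rxn_id, atp_rxn_id),
    sbml = read_model_sbml(path, biomass_rxn_id, atp_rxn_id)
  )
}

#' Save a constraint-based model
#'
#' @param model A [metnet_model()].
#' @param path Output path (reactions TSV for `format = "tsv"`).
#' @param format One of `"tsv"`, `"json"`, `"sbml"`.
#' @inheritParams load_model
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("tsv", "json", "sbml"),
                       metabolites_path = NULL) {
  format <- match.arg(format)
  switch(format,
    tsv = write_model_tsv(model, path, metabolites_path),
    json = write_model_json(model, path),
    sbml = write_model_sbml(model, path)
  )
  invisible(path)
}

default_metabolites_path <- function(reactions_path) {
  if (grepl("reactions", basename(reactions_path))) {
    file.path(dirname(reactions_path),
              sub("reactions", "metabolites", basename(reactions_path)))
  } else {
    file.path(dirname(reactions_path), "metabolites.tsv")
  }
}

# --- tabular dialect ---------------------------------------------------------

#' Parse a reaction equation string
#'
#' Accepts `"2 a[c] + b[c] -> c[c]"` with `"->"` (irreversible notation) or
#' `"<->"`/`"<=>"`; either side may be empty (exchange/demand reactions).
#' Bounds remain authoritative for reversibility; the arrow is notation only.
#'
#' @param eq Equation string.
#' @return Tibble with `metabolite`, `coefficient`.
#' @export
parse_equation <- function(eq) {
  arrow <- regmatches(eq, regexpr("<->|<=>|-->|->", eq))
  if (length(arrow) == 0L) {
    abort(paste0("equation has no arrow ('->' or '<->'): ", eq),
          class = "actd_format_error")
  }
  sides <- strsplit(eq, "<->|<=>|-->|->")[[1]]
  lhs <- if (length(sides) >= 1L) sides[[1]] else ""
  rhs <- if (length(sides) >= 2L) sides[[2]] else ""
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    terms <- trimws(strsplit(side, "\\s\\+\\s|^\\+\\s")[[1]])
    terms <- terms[nzchar(terms)]
    out <- map(terms, function(tm) {
      m <- regexec("^([0-9.]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S.*)$", tm)
      g <- regmatches(tm, m)[[1]]
      coef <- if (nzchar(trimws(g[2]))) as.numeric(trimws(g[2])) else 1
      tibble(metabolite = trimws(g[3]), coefficient = sign * coef)
    })
    bind_rows(out)
  }
  out <- bind_rows(parse_side(lhs, -1), parse_side(rhs, 1))
  if (is.null(out) || nrow(out) == 0L) {
    abort(paste0("equation has no metabolites: ", eq),
          class = "actd_format_error")
  }
  # a metabolite on both sides nets out
  out <- out |>
    group_by(.data$metabolite) |>
    summarise(coefficient = sum(.data$coefficient), .groups = "drop") |>
    filter(.data$coefficient != 0)
  out
}

#' Render a reaction's stoichiometry as an equation string
#' @param stoich Named numeric vector (metabolite id -> coefficient).
#' @param reversible Logical; selects the arrow.
#' @return Equation string.
#' @export
deparse_equation <- function(stoich, reversible = FALSE) {
  fmt <- function(v) {
    paste(ifelse(abs(v) == 1, names(v),
                 paste(format(abs(v), trim = TRUE, scientific = FALSE), names(v))),
          collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(if (length(lhs)) fmt(lhs) else "",
        if (reversible) "<->" else "->",
        if (length(rhs)) fmt(rhs) else "") |> trimws()
}

read_model_tsv <- function(path, metabolites_path = NULL,
                           biomass_rxn_id = NULL, atp_rxn_id = NULL) {
  rx <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), equation = readr::col_character(),
    lb = readr::col_double(), ub = readr::col_double(),
    .default = readr::col_character()))
  needed <- c("id", "equation", "lb", "ub")
  if (!all(needed %in% names(rx))) {
    abort(paste0("reactions TSV must have columns ",
                 paste(needed, collapse = ", "), ": ", path),
          class = "actd_format_error")
  }
  if (!"gpr" %in% names(rx)) rx$gpr <- ""
  conf <- if ("confidence" %in% names(rx)) rx[["confidence"]]
          else if ("confidence_class" %in% names(rx)) rx[["confidence_class"]]
          else NULL
  rx$confidence_class <- if (is.null(conf)) "other" else dplyr::coalesce(conf, "other")
  stoich_tab <- bind_rows(map(seq_len(nrow(rx)), function(i) {
    mutate(parse_equation(rx$equation[[i]]), reaction = rx$id[[i]])
  }))
  if (is.null(metabolites_path)) metabolites_path <- default_metabolites_path(path)
  mets <- if (file.exists(metabolites_path)) {
    readr::read_tsv(metabolites_path, col_types = readr::cols(.default = readr::col_character()))
  } else {
    tibble(id = sort(unique(stoich_tab$metabolite)))
  }
  metnet_model(
    metabolites = mets,
    reactions = select(rx, "id", "lb", "ub", "gpr", "confidence_class"),
    stoich = stoich_tab,
    biomass_rxn_id = biomass_rxn_id %||% abort("biomass_rxn_id is required for TSV models",
                                               class = "actd_config_error"),
    atp_rxn_id = atp_rxn_id %||% abort("atp_rxn_id is required for TSV models",
                                       class = "actd_config_error")
  )
}

write_model_tsv <- function(model, path, metabolites_path = NULL) {
  rx <- model$reactions
  S <- model$stoich
  eqs <- map_chr(rx$id, function(j) {
    col <- S[, j]
    deparse_equation(setNames(col[col != 0], rownames(S)[col != 0]),
                     reversible = rx$reversible[rx$id == j])
  })
  readr::write_tsv(tibble(id = rx$id, equation = eqs, lb = rx$lb, ub = rx$ub,
                          gpr = rx$gpr, confidence = rx$confidence_class), path)
  if (is.null(metabolites_path)) metabolites_path <- default_metabolites_path(path)
  readr::write_tsv(model$metabolites["id"], metabolites_path)
  invisible(path)
}

# --- JSON dialect ------------------------------------------------------------

read_model_json <- function(path, biomass_rxn_id = NULL, atp_rxn_id = NULL) {
  doc <- jsonlite::read_json(path)
  rx <- bind_rows(map(doc$reactions, function(r) {
    tibble(id = r$id, lb = r$lb, ub = r$ub, gpr = r$gpr %||% "",
           confidence_class = r$confidence_class %||% "other")
  }))
  stoich_tab <- bind_rows(map(doc$reactions, function(r) {
    tibble(reaction = r$id, metabolite = names(r$stoich),
           coefficient = as.numeric(unlist(r$stoich)))
  }))
  mets <- tibble(id = map_chr(doc$metabolites, "id"))
  metnet_model(mets, rx, stoich_tab,
               biomass_rxn_id = biomass_rxn_id %||% doc$biomass_rxn_id,
               atp_rxn_id = atp_rxn_id %||% doc$atp_rxn_id)
}

write_model_json <- function(model, path) {
  S <- model$stoich
  doc <- list(
    metabolites = map(model$metabolites$id, function(id) list(id = id)),
    reactions = map(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      col <- S[, r$id]
      list(id = r$id, lb = r$lb, ub = r$ub, gpr = r$gpr,
           confidence_class = r$confidence_class,
           stoich = as.list(setNames(col[col != 0], rownames(S)[col != 0])))
    }),
    biomass_rxn_id = model$biomass_rxn_id,
    atp_rxn_id = model$atp_rxn_id
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
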