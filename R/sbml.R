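# SBML Level 3 Version 1 + FBC v2 subset I/O, written directly with xml2.
# Covers the constructs constraint-based models need: compartments, species,
# reactions with parameter-backed flux bounds, gene product associations
# (and/or trees), an active maximization objective (biomass), and reaction
# notes carrying the confidence class. Original bracketed metabolite ids are
# kept in the `name` attribute so round-trips are lossless.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  rx <- model$reactions
  S <- model$stoich
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(v) format(v, trim = TRUE, scientific = FALSE, digits = 17)

  genes <- sort(unique(unlist(map(rx$gpr, function(g) {
    if (!nzchar(g)) character() else gpr_genes(parse_gpr(g))
  }))))

  gpa_xml <- function(node) {
    switch(node$op,
      gene = sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     sbml_safe(node$gene)),
      or = paste0("<fbc:or>", paste(map_chr(node$args, gpa_xml), collapse = ""),
                  "</fbc:or>"),
      and = paste0("<fbc:and>", paste(map_chr(node$args, gpa_xml), collapse = ""),
                   "</fbc:and>")
    )
  }
  spec_refs <- function(v) {
    paste(sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                  sbml_safe(names(v)), num(abs(unname(v)))), collapse = "")
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    '<model id="actd_model" fbc:strict="true">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('<p>atp_rxn_id: %s</p>', esc(model$atp_rxn_id)),
    '</body></notes>',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', sbml_safe(model$compartments)),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            sbml_safe(model$metabolites$id), esc(model$metabolites$id),
            sbml_safe(model$metabolites$compartment)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="lb_%s" value="%s" constant="true"/>',
            sbml_safe(rx$id), num(rx$lb)),
    sprintf('<parameter id="ub_%s" value="%s" constant="true"/>',
            sbml_safe(rx$id), num(rx$ub)),
    "</listOfParameters>",
    if (length(genes)) c(
      "<fbc:listOfGeneProducts>",
      sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              sbml_safe(genes), esc(genes)),
      "</fbc:listOfGeneProducts>"
    ),
    "<listOfReactions>"
  )
  for (i in seq_len(nrow(rx))) {
    col <- S[, rx$id[[i]]]
    st <- setNames(col[col != 0], rownames(S)[col != 0])
    body <- c(
      sprintf('<reaction id="R_%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
              sbml_safe(rx$id[[i]]), esc(rx$id[[i]]),
              tolower(as.character(rx$reversible[[i]])),
              sbml_safe(rx$id[[i]]), sbml_safe(rx$id[[i]])),
      sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>confidence_class: %s</p></body></notes>',
              rx$confidence_class[[i]]),
      if (any(st < 0)) paste0("<listOfReactants>", spec_refs(st[st < 0]), "</listOfReactants>"),
      if (any(st > 0)) paste0("<listOfProducts>", spec_refs(st[st > 0]), "</listOfProducts>"),
      if (nzchar(rx$gpr[[i]])) paste0("<fbc:geneProductAssociation>",
                                      gpa_xml(parse_gpr(rx$gpr[[i]])),
                                      "</fbc:geneProductAssociation>"),
      "</reaction>"
    )
    lines <- c(lines, body)
  }
  lines <- c(lines,
    "</listOfReactions>",
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    "<fbc:listOfFluxObjectives>",
    sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            sbml_safe(model$biomass_rxn_id)),
    "</fbc:listOfFluxObjectives>",
    "</fbc:objective>",
    "</fbc:listOfObjectives>",
    "</model>",
    "</sbml>"
  )
  # parse once so malformed output can never be written silently
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

xattr <- function(node, name) {
  a <- xml2::xml_attr(node, name)
  if (is.na(a)) xml2::xml_attr(node, sub("^.*:", "", name)) else a
}

read_model_sbml <- function(path, biomass_rxn_id = NULL, atp_rxn_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("SBML parse failure in ", path, ": ", conditionMessage(e)),
          class = "actd_format_error")
  })
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mdl, "xml_missing")) {
    abort("no <model> element found", class = "actd_format_error")
  }

  sp_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  met_id <- ifelse(!is.na(sp_name) & grepl("\\[[^][]+\\]$", sp_name), sp_name,
                   paste0(sub("^M_", "", sp_id), "[", sp_comp, "]"))
  sp_map <- setNames(met_id, sp_id)

  par_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_map <- setNames(
    ifelse(is.na(xattr_all(gp_nodes, "label")),
           sub("^G_", "", xattr_all(gp_nodes, "id")),
           xattr_all(gp_nodes, "label")),
    xattr_all(gp_nodes, "id"))

  gpa_to_string <- function(node, top = TRUE) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xattr(node, "fbc:geneProduct")
      return(if (ref %in% names(gp_map)) gp_map[[ref]] else sub("^G_", "", ref))
    }
    kids <- xml2::xml_children(node)
    parts <- map_chr(kids, gpa_to_string, top = FALSE)
    joined <- paste(parts, collapse = if (nm == "or") " or " else " and ")
    if (top) joined else paste0("(", joined, ")")
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rows <- map(rx_nodes, function(nd) {
    rid_raw <- xml2::xml_attr(nd, "id")
    nm <- xml2::xml_attr(nd, "name")
    rid <- if (!is.na(nm) && nzchar(nm)) nm else sub("^R_", "", rid_raw)
    lbp <- xattr(nd, "fbc:lowerFluxBound")
    ubp <- xattr(nd, "fbc:upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else
      if (isTRUE(xml2::xml_attr(nd, "reversible") == "true")) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(nd, xp)
      if (length(sr) == 0L) return(NULL)
      tibble(reaction = rid,
             metabolite = unname(sp_map[xml2::xml_attr(sr, "species")]),
             coefficient = sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
    gpa <- xml2::xml_find_first(nd, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else
      gpa_to_string(xml2::xml_child(gpa))
    notes <- xml2::xml_text(xml2::xml_find_all(nd, ".//*[local-name()='notes']//*[local-name()='p']"))
    conf <- sub("^\\s*confidence_class:\\s*", "",
                grep("confidence_class:", notes, value = TRUE))
    list(rx = tibble(id = rid, lb = lb, ub = ub, gpr = gpr,
                     confidence_class = if (length(conf)) conf[[1]] else "other"),
         st = bind_rows(refs(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1),
                        refs(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", 1)))
  })
  rx <- bind_rows(map(rows, "rx"))
  stoich_tab <- bind_rows(map(rows, "st"))

  if (is.null(biomass_rxn_id)) {
    fo <- xml2::xml_find_first(mdl, ".//*[local-name()='listOfObjectives']//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) {
      ref <- xattr(fo, "fbc:reaction")
      hit <- match(ref, paste0("R_", sbml_safe(rx$id)))
      biomass_rxn_id <- if (!is.na(hit)) rx$id[[hit]] else sub("^R_", "", ref)
    }
  }
  if (is.null(atp_rxn_id)) {
    notes <- xml2::xml_text(xml2::xml_find_all(mdl, "./*[local-name()='notes']//*[local-name()='p']"))
    hit <- grep("atp_rxn_id:", notes, value = TRUE)
    if (length(hit)) atp_rxn_id <- sub("^\\s*atp_rxn_id:\\s*", "", hit[[1]])
  }
  if (is.null(biomass_rxn_id) || is.null(atp_rxn_id)) {
    abort("biomass/ATP reaction ids not found in SBML; pass them explicitly",
          class = "actd_config_error")
  }
  metnet_model(tibble(id = unname(met_id)), rx, stoich_tab,
               biomass_rxn_id, atp_rxn_id)
}

xattr_all <- function(nodes, name) {
  a <- xml2::xml_attr(nodes, name)
  b <- xml2::xml_attr(nodes, paste0("fbc:", name))
  ifelse(is.na(a), b, a)
}
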