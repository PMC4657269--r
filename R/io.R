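# Readers and writers for reaction universes (COBRA JSON, SBML Level 3
# FBC, plain tabular dialect) and for environment definitions (YAML/JSON).
#
# Orientation convention: pseudo-exchange columns are normalised so that
# positive flux means uptake into the system (supply coefficient +1).
# Exchanges written by BiGG-style tools ("met_e ->", coefficient -1) are
# flipped on load.

RCFBA_XMLNS <- "https://rcfba.invalid/ns/1"

guessFormat <- function(path) {
  switch(tolower(tools::file_ext(path)),
         xml = , sbml = "sbml",
         json = "cobra_json",
         tsv = , txt = "tsv",
         stop("cannot guess model format from extension of '", path,
              "'; pass format explicitly"))
}

# identify the biomass reaction among candidate ids
pickBiomass <- function(ids, objective, biomass) {
  if (!is.null(biomass)) {
    if (!biomass %in% ids) stop("biomass reaction '", biomass,
                                "' not found in model")
    return(biomass)
  }
  obj <- ids[objective != 0]
  if (length(obj) == 1) return(obj)
  cand <- ids[grepl("biomass", ids, ignore.case = TRUE)]
  if (length(cand) == 1) return(cand)
  stop("no biomass reaction identifiable (no unique objective reaction or ",
       "id matching 'biomass'); pass biomass = \"<reaction id>\"")
}

finalizeUniverse <- function(mets, rxns, sto, biomass, carriers, nGenes = NA) {
  # classify: biomass first, then single-metabolite reactions are exchanges
  nmet <- vapply(sto, function(s) length(s[s != 0]), integer(1))
  kind <- rep("enzymatic", nrow(rxns))
  kind[rxns$id == biomass] <- "biomass"
  kind[nmet == 1 & rxns$id != biomass &
         is.na(rxns$kindHint)] <- "pseudo_exchange"
  kind[!is.na(rxns$kindHint)] <- rxns$kindHint[!is.na(rxns$kindHint)]
  # normalise exchange orientation to uptake-positive
  for (j in which(kind == "pseudo_exchange")) {
    s <- sto[[j]][sto[[j]] != 0]
    if (length(s) == 1 && s < 0) sto[[j]] <- -sto[[j]]
  }
  rxns$kind <- kind
  rxns$reversible[kind == "pseudo_exchange"] <- FALSE
  rxns$alpha[is.na(rxns$alpha)] <- 1
  rxns$beta[is.na(rxns$beta)] <-
    ifelse(rxns$reversible[is.na(rxns$beta)], 1, 0)
  rxns$beta[rxns$kind != "pseudo_exchange" & !rxns$reversible] <- 0
  rxns$kindHint <- NULL
  mets$isCarrier <- mets$id %in% carriers
  u <- reactionUniverse(mets, rxns, sto)
  attr(u, "nGenes") <- nGenes
  u
}

#' Read a reaction universe from file
#'
#' Supports COBRA JSON, SBML Level 3 (FBC objectives) and the package's
#' tabular dialect (see [writeUniverse()]). Boundary reactions (a single
#' metabolite) are classified as costless pseudo-exchanges and normalised
#' to uptake-positive orientation; the biomass reaction is taken from the
#' model objective, an id matching \sQuote{biomass}, or the
#' \code{biomass} argument. Catalytic rates default to \code{alpha = 1}
#' and \code{beta = 1} (reversible) or 0 (irreversible) when the file
#' does not carry them.
#'
#' @param path file path
#' @param format \code{"auto"} (by extension), \code{"sbml"},
#'   \code{"cobra_json"} or \code{"tsv"}
#' @param biomass optional biomass reaction id when the model does not
#'   identify one
#' @param carriers metabolite ids flagged as carriers (default
#'   [defaultCarriers()])
#' @return a [ReactionUniverse-class]; the gene count of the source model
#'   (when annotated) is attached as attribute \code{"nGenes"}
#' @export
readUniverse <- function(path, format = c("auto", "sbml", "cobra_json", "tsv"),
                         biomass = NULL, carriers = defaultCarriers()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         cobra_json = readCobraJson(path, biomass, carriers),
         sbml = readSbml(path, biomass, carriers),
         tsv = readTsvUniverse(path, biomass, carriers))
}

#' Write a reaction universe to file
#'
#' The tabular dialect has one reaction per line with tab-separated
#' columns \code{id}, \code{kind}, \code{reversible}, \code{alpha},
#' \code{beta}, \code{equation} (e.g. \code{"2 A + B -> C"}; exchanges
#' are written \code{"-> S1"}). \code{#} starts a comment; directive
#' lines \code{@external} and \code{@carriers} list the external and
#' carrier metabolites. COBRA JSON and SBML carry kinds and rates in
#' annotations so that a round trip reproduces stoichiometry, kinds,
#' reversibility and rates exactly.
#'
#' @param universe a [ReactionUniverse-class]
#' @param path output file path
#' @param format \code{"auto"}, \code{"sbml"}, \code{"cobra_json"} or
#'   \code{"tsv"}
#' @return \code{path}, invisibly
#' @export
writeUniverse <- function(universe, path,
                          format = c("auto", "sbml", "cobra_json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guessFormat(path)
  switch(format,
         cobra_json = writeCobraJson(universe, path),
         sbml = writeSbml(universe, path),
         tsv = writeTsvUniverse(universe, path))
  invisible(path)
}

## ---- COBRA JSON ----

readCobraJson <- function(path, biomass, carriers) {
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("unparseable COBRA JSON '", path, "': ",
                       conditionMessage(e)))
  if (is.null(j$metabolites) || is.null(j$reactions))
    stop("COBRA JSON '", path, "' lacks metabolites/reactions elements")
  mets <- data.frame(
    id = vapply(j$metabolites, function(m) m$id, ""),
    name = vapply(j$metabolites, function(m) m$name %||% m$id, ""))
  comp <- vapply(j$metabolites, function(m) m$compartment %||% "", "")
  mets$isExternal <- comp %in% c("e", "e0", "extracellular") |
    grepl("_e$", mets$id)
  ann <- function(rr, key) {
    v <- rr$annotation[[key]]
    if (is.null(v)) NA else as.vector(v)
  }
  rxns <- data.frame(
    id = vapply(j$reactions, function(rr) rr$id, ""),
    name = vapply(j$reactions, function(rr) rr$name %||% rr$id, ""),
    reversible = vapply(j$reactions, function(rr) {
      rev <- ann(rr, "reversible")
      if (!is.na(rev)) as.logical(rev) else (rr$lower_bound %||% 0) < 0
    }, logical(1)),
    alpha = vapply(j$reactions, function(rr) as.numeric(ann(rr, "alpha")),
                   numeric(1)),
    beta = vapply(j$reactions, function(rr) as.numeric(ann(rr, "beta")),
                  numeric(1)),
    kindHint = vapply(j$reactions, function(rr) as.character(ann(rr, "kind")),
                      character(1)))
  sto <- lapply(j$reactions, function(rr)
    vapply(rr$metabolites, as.numeric, numeric(1)))
  obj <- vapply(j$reactions, function(rr)
    as.numeric(rr$objective_coefficient %||% 0), numeric(1))
  bm <- pickBiomass(rxns$id, obj, biomass)
  nGenes <- if (length(j$genes)) length(j$genes) else NA_integer_
  finalizeUniverse(mets, rxns, sto, bm, carriers, nGenes)
}

writeCobraJson <- function(universe, path) {
  met <- universe@metabolites; rxn <- universe@reactions; S <- universe@S
  mets <- lapply(seq_len(nrow(met)), function(i) list(
    id = met$id[i], name = met$name[i],
    compartment = if (met$isExternal[i]) "e" else "c"))
  rxns <- lapply(seq_len(nrow(rxn)), function(j) {
    col <- S[, j]
    sto <- as.list(col[col != 0])
    list(id = rxn$id[j], name = rxn$name[j], metabolites = sto,
         lower_bound = if (rxn$reversible[j] ||
                           rxn$kind[j] == "pseudo_exchange") -1000 else 0,
         upper_bound = 1000,
         objective_coefficient = if (rxn$kind[j] == "biomass") 1 else 0,
         annotation = list(kind = rxn$kind[j], reversible = rxn$reversible[j],
                           # %.17g strings survive the round trip bit-exactly
                           alpha = sprintf("%.17g", rxn$alpha[j]),
                           beta = sprintf("%.17g", rxn$beta[j])))
  })
  jsonlite::write_json(list(id = "rcfba_model", metabolites = mets,
                            reactions = rxns, genes = list(),
                            compartments = list(c = "cytosol",
                                                e = "extracellular")),
                       path, auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tabular dialect ----

parseEquationSide <- function(side) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  out <- numeric(0)
  for (tt in terms) {
    parts <- strsplit(trimws(tt), "\\s+")[[1]]
    if (length(parts) == 1) {
      out[parts[1]] <- (out[parts[1]] %||na% 0) + 1
    } else if (length(parts) == 2 &&
               !is.na(suppressWarnings(as.numeric(parts[1])))) {
      out[parts[2]] <- (out[parts[2]] %||na% 0) + as.numeric(parts[1])
    } else stop("cannot parse equation term '", tt, "'")
  }
  out
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

parseEquation <- function(eq, line) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2 || !grepl("->", eq, fixed = TRUE))
    stop("line ", line, ": equation must contain exactly one '->': '", eq, "'")
  lhs <- parseEquationSide(sides[1])
  rhs <- if (length(sides) == 2) parseEquationSide(sides[2]) else numeric(0)
  sto <- numeric(0)
  for (m in names(lhs)) sto[m] <- -lhs[[m]]
  for (m in names(rhs)) sto[m] <- (sto[m] %||na% 0) + rhs[[m]]
  sto[sto != 0]
}

readTsvUniverse <- function(path, biomass, carriers) {
  lines <- readLines(path)
  external <- character(0); fileCarriers <- character(0)
  metOrder <- character(0)
  recs <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(raw))) next
    if (grepl("^@metabolites\\b", raw)) {
      metOrder <- c(metOrder, strsplit(trimws(sub("^@metabolites", "", raw)),
                                       "\\s+")[[1]])
      next
    }
    if (grepl("^@external\\b", raw)) {
      external <- c(external, strsplit(trimws(sub("^@external", "", raw)),
                                       "\\s+")[[1]])
      next
    }
    if (grepl("^@carriers\\b", raw)) {
      fileCarriers <- c(fileCarriers,
                        strsplit(trimws(sub("^@carriers", "", raw)),
                                 "\\s+")[[1]])
      next
    }
    f <- strsplit(raw, "\t")[[1]]
    if (length(f) < 6)
      stop("line ", ln, ": expected 6 tab-separated fields ",
           "(id, kind, reversible, alpha, beta, equation), got ", length(f))
    if (!f[2] %in% REACTION_KINDS)
      stop("line ", ln, ": unknown reaction kind '", f[2], "'")
    recs[[length(recs) + 1]] <- list(
      id = trimws(f[1]), kind = trimws(f[2]),
      reversible = as.logical(trimws(f[3])),
      alpha = as.numeric(f[4]), beta = as.numeric(f[5]),
      sto = parseEquation(f[6], ln))
  }
  if (!length(recs)) stop("no reactions found in '", path, "'")
  metIds <- unique(c(metOrder,
                     unlist(lapply(recs, function(rr) names(rr$sto)))))
  mets <- data.frame(id = metIds, name = metIds,
                     isExternal = metIds %in% external)
  rxns <- data.frame(id = vapply(recs, `[[`, "", "id"),
                     name = vapply(recs, `[[`, "", "id"),
                     reversible = vapply(recs, `[[`, NA, "reversible"),
                     alpha = vapply(recs, `[[`, 0, "alpha"),
                     beta = vapply(recs, `[[`, 0, "beta"),
                     kindHint = vapply(recs, `[[`, "", "kind"))
  sto <- lapply(recs, `[[`, "sto")
  hasBm <- any(rxns$kindHint == "biomass")
  bm <- if (hasBm) rxns$id[rxns$kindHint == "biomass"][1]
        else if (!is.null(biomass)) biomass else NA
  if (is.na(bm)) bm <- "" # universe without biomass (allowed at load)
  finalizeUniverse(mets, rxns, sto, bm,
                   union(carriers, fileCarriers))
}

formatEquation <- function(sto) {
  fmtSide <- function(s) {
    if (!length(s)) return("")
    paste(vapply(seq_along(s), function(i) {
      cf <- abs(s[[i]])
      if (cf == 1) names(s)[i] else paste(sprintf("%.17g", cf), names(s)[i])
    }, ""), collapse = " + ")
  }
  lhs <- sto[sto < 0]; rhs <- sto[sto > 0]
  paste(fmtSide(lhs), "->", fmtSide(rhs))
}

writeTsvUniverse <- function(universe, path) {
  met <- universe@metabolites; rxn <- universe@reactions; S <- universe@S
  lines <- c("# rcfba reaction universe",
             "# id\tkind\treversible\talpha\tbeta\tequation",
             paste("@metabolites", paste(met$id, collapse = " ")))
  if (any(met$isExternal))
    lines <- c(lines, paste("@external",
                            paste(met$id[met$isExternal], collapse = " ")))
  if (any(met$isCarrier))
    lines <- c(lines, paste("@carriers",
                            paste(met$id[met$isCarrier], collapse = " ")))
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]
    lines <- c(lines, paste(rxn$id[j], rxn$kind[j], rxn$reversible[j],
                            sprintf("%.17g", rxn$alpha[j]),
                            sprintf("%.17g", rxn$beta[j]),
                            formatEquation(col[col != 0]), sep = "\t"))
  }
  writeLines(lines, path)
}

## ---- SBML Level 3 (FBC) ----

readSbml <- function(path, biomass, carriers) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (!length(sp)) stop("SBML '", path, "' contains no species")
  metId <- xml2::xml_attr(sp, "id")
  metName <- xml2::xml_attr(sp, "name")
  metComp <- xml2::xml_attr(sp, "compartment")
  rx <- xml2::xml_find_all(
    doc, ".//*[local-name()='reaction']")
  if (!length(rx)) stop("SBML '", path, "' contains no reactions")
  rxId <- xml2::xml_attr(rx, "id")
  # strip conventional SBML prefixes when used consistently
  stripM <- all(grepl("^M_", metId)); stripR <- all(grepl("^R_", rxId))
  mid <- if (stripM) sub("^M_", "", metId) else metId
  rid <- if (stripR) sub("^R_", "", rxId) else rxId
  sto <- vector("list", length(rx))
  for (j in seq_along(rx)) {
    s <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        rx[[j]], sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                         side))
      if (!length(refs)) next
      ids <- xml2::xml_attr(refs, "species")
      if (stripM) ids <- sub("^M_", "", ids)
      cf <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      cf[is.na(cf)] <- 1
      if (side == "listOfReactants") cf <- -cf
      for (i in seq_along(ids)) s[ids[i]] <- (s[ids[i]] %||na% 0) + cf[i]
    }
    sto[[j]] <- s
  }
  info <- lapply(rx, function(node) {
    ann <- xml2::xml_find_first(node, ".//*[local-name()='universeInfo']")
    if (inherits(ann, "xml_missing")) return(list(NA, NA, NA))
    list(xml2::xml_attr(ann, "kind"),
         as.numeric(xml2::xml_attr(ann, "alpha")),
         as.numeric(xml2::xml_attr(ann, "beta")))
  })
  rxns <- data.frame(
    id = rid,
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), rid,
                  xml2::xml_attr(rx, "name")),
    reversible = xml2::xml_attr(rx, "reversible") %in% c("true", "1"),
    alpha = vapply(info, function(x) as.numeric(x[[2]]), numeric(1)),
    beta = vapply(info, function(x) as.numeric(x[[3]]), numeric(1)),
    kindHint = vapply(info, function(x) as.character(x[[1]]), character(1)))
  # fbc objective
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  objIds <- xml2::xml_attr(fo, "reaction")
  if (stripR) objIds <- sub("^R_", "", objIds)
  obj <- as.numeric(rid %in% objIds)
  mets <- data.frame(id = mid,
                     name = ifelse(is.na(metName), mid, metName),
                     isExternal = metComp %in% c("e", "e0", "extracellular") |
                       grepl("_e$", mid))
  bm <- pickBiomass(rid, obj, biomass)
  finalizeUniverse(mets, rxns, sto, bm, carriers)
}

xmlNum <- function(x) sprintf("%.17g", x)

writeSbml <- function(universe, path) {
  met <- universe@metabolites; rxn <- universe@reactions; S <- universe@S
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="rcfba_model" fbc:strict="false">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(met)))
    out <- c(out, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(met$id[i]), esc(met$name[i]), if (met$isExternal[i]) "e" else "c"))
  out <- c(out, '    </listOfSpecies>', '    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]; col <- col[col != 0]
    out <- c(out, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false">',
      esc(rxn$id[j]), esc(rxn$name[j]),
      tolower(as.character(rxn$reversible[j]))))
    out <- c(out, '        <annotation>',
             sprintf('          <universeInfo xmlns="%s" kind="%s" alpha="%s" beta="%s"/>',
                     RCFBA_XMLNS, rxn$kind[j], xmlNum(rxn$alpha[j]),
                     xmlNum(rxn$beta[j])),
             '        </annotation>')
    subs <- col[col < 0]; prods <- col[col > 0]
    if (length(subs)) {
      out <- c(out, '        <listOfReactants>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(names(subs)), xmlNum(abs(subs))),
               '        </listOfReactants>')
    }
    if (length(prods)) {
      out <- c(out, '        <listOfProducts>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(names(prods)), xmlNum(prods)),
               '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  bm <- biomassId(universe)
  if (!is.na(bm))
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              esc(bm)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path)
}

## ---- environment configs ----

#' Read environment definitions from a YAML or JSON config
#'
#' Schema: \code{conditions: [\{name, unbounded: [ids], bounds:
#' \{id: value\}\}]}; ids are pseudo-exchange reaction ids, values are
#' finite upper bounds, \code{unbounded} lists nutrients with no upper
#' bound.
#'
#' @param path config file (\code{.yaml}/\code{.yml}/\code{.json})
#' @return an [EnvironmentSet-class]
#' @export
readEnvironments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$conditions)) stop("config lacks a 'conditions' list")
  conds <- list()
  for (cc in cfg$conditions) {
    if (is.null(cc$name)) stop("every condition needs a 'name'")
    b <- numeric(0)
    for (id in cc$unbounded %||% list()) b[[id]] <- Inf
    for (id in names(cc$bounds %||% list()))
      b[[id]] <- as.numeric(cc$bounds[[id]])
    conds[[cc$name]] <- b
  }
  environmentSet(conds)
}

#' Write environment definitions to a YAML or JSON config
#'
#' @param envs an [EnvironmentSet-class]
#' @param path output path; format chosen by extension
#' @return \code{path}, invisibly
#' @export
writeEnvironments <- function(envs, path) {
  conds <- lapply(conditionNames(envs), function(nm) {
    b <- envs@conditions[[nm]]
    list(name = nm,
         unbounded = as.list(names(b)[is.infinite(b)]),
         bounds = as.list(b[is.finite(b)]))
  })
  cfg <- list(conditions = conds)
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}
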