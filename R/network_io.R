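# Metabolic network container, tab-separated interchange format, minimal SBML
# reader, and the reversible-reaction split used by the enumeration engine.

#' Metabolic network
#'
#' A metabolic network over internal metabolites only: external metabolites
#' act as open sources and sinks and are omitted, so the stoichiometric
#' matrix `S` (rows = internal metabolites, columns = reactions) carries the
#' complete steady-state constraint `S v = 0`.
#'
#' @param metabolite_ids character vector of internal metabolite identifiers.
#' @param reaction_ids character vector of unique reaction identifiers.
#' @param reversible logical vector, one flag per reaction.
#' @param S stoichiometric matrix: a numeric matrix of integer-valued or
#'   decimal coefficients, or a `rat` matrix; coerced to exact rationals.
#' @param reaction_names optional free-text names, defaults to the ids.
#' @return an object of class `"metabolic_network"`.
#' @export
metabolic_network <- function(metabolite_ids, reaction_ids, reversible, S,
                              reaction_names = reaction_ids) {
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (length(reaction_ids) == 0 || length(metabolite_ids) == 0)
    stop("empty network", call. = FALSE)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids", call. = FALSE)
  if (any(!nzchar(reaction_ids)) || any(!nzchar(metabolite_ids)))
    stop("empty identifier", call. = FALSE)
  if (length(reversible) != length(reaction_ids))
    stop("reversibility flags do not match reaction count", call. = FALSE)
  if (!inherits(S, "rat")) {
    if (!is.matrix(S)) stop("S must be a matrix", call. = FALSE)
    S <- rat_parse(format(S, scientific = FALSE))
    S <- new_rat(matrix(S$num, length(metabolite_ids)),
                 matrix(S$den, length(metabolite_ids)))
  }
  if (nrow(S$num) != length(metabolite_ids))
    stop("S row count does not match metabolite count", call. = FALSE)
  if (ncol(S$num) != length(reaction_ids))
    stop("S column count does not match reaction count", call. = FALSE)
  if (any(colSums(S$num != 0) == 0))
    stop("all-zero reaction column in S", call. = FALSE)
  structure(list(metabolite_ids = metabolite_ids,
                 reaction_ids = reaction_ids,
                 reaction_names = as.character(reaction_names),
                 reversible = as.logical(reversible),
                 S = S),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network:", length(x$metabolite_ids), "internal metabolites,",
      length(x$reaction_ids), "reactions (",
      sum(x$reversible), "reversible )\n")
  invisible(x)
}

#' Read a metabolic network
#'
#' Reads the package's tab-separated network format or a (minimal subset of)
#' SBML Level 2/3.  The tsv dialect has a first header row `#` followed by
#' the reaction ids, a second header row `#rev` with 0/1 reversibility
#' flags, and then one row per internal metabolite: the metabolite id
#' followed by the stoichiometric coefficients (integers, decimals, or `p/q`
#' rationals).
#'
#' @param path path to the network file.
#' @param format `"tsv"`, `"sbml"`, or `"auto"` (by file extension).
#' @param external_compartments for SBML: compartment ids whose species are
#'   treated as external in addition to species with
#'   `boundaryCondition="true"`.
#' @return a [metabolic_network()].
#' @export
read_network <- function(path, format = c("auto", "tsv", "sbml"),
                         external_compartments = character(0)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "tsv"
  }
  if (format == "tsv") read_network_tsv(path) else
    read_network_sbml(path, external_compartments)
}

read_network_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("network file too short: ", path, call. = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rev <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "#" || rev[1] != "#rev")
    stop("network tsv must start with '#' and '#rev' header rows", call. = FALSE)
  rxn_ids <- hdr[-1]
  rev_flags <- rev[-1]
  if (length(rev_flags) != length(rxn_ids))
    stop("#rev row length does not match reaction header", call. = FALSE)
  if (!all(rev_flags %in% c("0", "1")))
    stop("reversibility flags must be 0 or 1", call. = FALSE)
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  met_ids <- vapply(body, `[`, "", 1)
  coefs <- lapply(body, function(row) {
    if (length(row) != length(rxn_ids) + 1)
      stop("metabolite row '", row[1], "' has ", length(row) - 1,
           " coefficients, expected ", length(rxn_ids), call. = FALSE)
    row[-1]
  })
  v <- rat_parse(unlist(coefs))
  S <- new_rat(matrix(v$num, nrow = length(met_ids), byrow = TRUE),
               matrix(v$den, nrow = length(met_ids), byrow = TRUE))
  metabolic_network(met_ids, rxn_ids, rev_flags == "1", S)
}

#' Write a metabolic network as tsv
#'
#' Inverse of the tsv branch of [read_network()]; exact rational
#' coefficients are written as `p/q` so that a read round trip reproduces
#' the network bit-exactly.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  lines <- c(paste(c("#", net$reaction_ids), collapse = "\t"),
             paste(c("#rev", as.integer(net$reversible)), collapse = "\t"))
  fm <- format(net$S)
  for (i in seq_along(net$metabolite_ids)) {
    lines <- c(lines, paste(c(net$metabolite_ids[i], fm[i, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Minimal SBML reader: species ids/compartments/boundaryCondition and
# reaction reversibility + stoichiometry.  Namespace handled by stripping.
read_network_sbml <- function(path, external_compartments = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0) stop("no species in SBML file", call. = FALSE)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_bc <- tolower(ifelse(is.na(xml2::xml_attr(sp, "boundaryCondition")),
                          "false", xml2::xml_attr(sp, "boundaryCondition")))
  external <- sp_bc == "true" | sp_comp %in% external_compartments
  internal_ids <- sp_id[!external]
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx) == 0) stop("no reactions in SBML file", call. = FALSE)
  rx_id <- xml2::xml_attr(rx, "id")
  rx_name <- xml2::xml_attr(rx, "name")
  rx_name[is.na(rx_name)] <- rx_id[is.na(rx_name)]
  # SBML default for 'reversible' is true
  rx_rev <- tolower(ifelse(is.na(xml2::xml_attr(rx, "reversible")),
                           "true", xml2::xml_attr(rx, "reversible")))
  S <- matrix(0, nrow = length(internal_ids), ncol = length(rx),
              dimnames = list(internal_ids, rx_id))
  add_refs <- function(j, refs, sgn) {
    for (ref in refs) {
      species <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      st <- if (is.na(st)) 1 else as.numeric(st)
      if (species %in% internal_ids)
        S[species, j] <<- S[species, j] + sgn * st
    }
  }
  for (j in seq_along(rx)) {
    add_refs(j, xml2::xml_find_all(rx[[j]], "./listOfReactants/speciesReference"), -1)
    add_refs(j, xml2::xml_find_all(rx[[j]], "./listOfProducts/speciesReference"), +1)
  }
  drop_rows <- rowSums(S != 0) == 0
  if (any(drop_rows)) {
    warning("dropping ", sum(drop_rows),
            " internal species that take part in no reaction")
    S <- S[!drop_rows, , drop = FALSE]
    internal_ids <- internal_ids[!drop_rows]
  }
  metabolic_network(internal_ids, rx_id, rx_rev == "true", S,
                    reaction_names = rx_name)
}

#' Split reversible reactions
#'
#' Produces the all-irreversible extended network: every reversible reaction
#' column is duplicated with negated sign, the backward copy placed directly
#' after the forward one (`Xf`, `Xb`).  The flux cone of the extended
#' network is pointed, which is what lets intermediate modes be stored as
#' bit vectors: a set flux bit can never be cleared again by combining
#' modes.
#'
#' @param net a [metabolic_network()].
#' @return an object of class `"extended_network"`: the base network, the
#'   extended matrix `S_ext`, the extended column ids, and `col_map`
#'   (original reaction id -> extended column id(s)).
#' @export
split_reversibles <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  cols <- list(); ids <- character(0); col_map <- list(); origin <- character(0)
  for (j in seq_along(net$reaction_ids)) {
    id <- net$reaction_ids[j]
    cj <- net$S[, j, drop = FALSE]
    if (net$reversible[j]) {
      fid <- paste0(id, "f"); bid <- paste0(id, "b")
      cols <- c(cols, list(cj, -cj))
      ids <- c(ids, fid, bid)
      origin <- c(origin, id, id)
      col_map[[id]] <- c(fid, bid)
    } else {
      cols <- c(cols, list(cj))
      ids <- c(ids, id)
      origin <- c(origin, id)
      col_map[[id]] <- id
    }
  }
  S_ext <- do.call(rat_cbind, cols)
  structure(list(base = net, S_ext = S_ext, ext_ids = ids,
                 ext_origin = origin, col_map = col_map),
            class = "extended_network")
}

#' @export
print.extended_network <- function(x, ...) {
  cat("Extended (all-irreversible) network:", length(x$ext_ids),
      "columns over", length(x$base$reaction_ids), "original reactions\n")
  invisible(x)
}

# Undo the split: the forward column of each reversible pair is the
# original column (the backward one is its negation).  Round-trip check.
merge_extended_matrix <- function(ext) {
  cols <- lapply(ext$base$reaction_ids, function(id) {
    idx <- match(ext$col_map[[id]][1], ext$ext_ids)
    ext$S_ext[, idx, drop = FALSE]
  })
  do.call(rat_cbind, cols)
}
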