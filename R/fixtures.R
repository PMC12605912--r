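#' Names of the ten packaged breast-cancer drugs
#'
#' @return Character vector of display names, in the packaged table order.
#' @export
drug_names <- function() {
  expected_invariants()$drug
}

fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "resolvti", mustWork = FALSE)
  if (!nzchar(p)) {
    stop(sprintf("fixture-integrity error: missing packaged file '%s'",
                 file.path(...)), call. = FALSE)
  }
  p
}

drug_file_stem <- function(drug) gsub(" ", "_", tolower(drug))

#' Load the packaged molecular graph of one drug
#'
#' @param drug display name (e.g. \code{"Thiotepa"}, \code{"Megestrol
#'   Acetate"}), case-insensitive.
#' @return A \code{\link{molecular_graph}} named with the display name.
#' @export
load_drug_graph <- function(drug) {
  known <- drug_names()
  hit <- match(tolower(drug), tolower(known))
  if (is.na(hit)) {
    stop(sprintf("unknown drug '%s'; packaged drugs: %s", drug,
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  drug <- known[hit]
  load_edge_list(fixture_path("drugs", paste0(drug_file_stem(drug), ".edges")),
                 name = drug)
}

#' Packaged physicochemical property table
#'
#' Molar volume (MV, cm^3), polarizability (P, cm^3), molar refractivity
#' (MR, cm^3), polar surface area (PSA, Angstrom^2) and surface tension
#' (ST, dyne/cm) for the ten drugs.
#'
#' @return Data frame with columns \code{drug}, \code{MV}, \code{P},
#'   \code{MR}, \code{PSA}, \code{ST}.
#' @export
drug_properties <- function() {
  tab <- utils::read.csv(fixture_path("properties.csv"))
  stopifnot(all(qspr_properties %in% names(tab)))
  if (any(as.matrix(tab[qspr_properties]) <= 0)) {
    stop("fixture-integrity error: non-positive property value", call. = FALSE)
  }
  tab
}

#' Published graph-invariant table (expected values)
#'
#' The expected tuple (|V|, |E|, beta, eta, xi1, xi2) per drug, used as the
#' oracle for the exhaustive solver.
#'
#' @return Data frame with columns \code{drug}, \code{n_vertices},
#'   \code{n_edges}, \code{beta}, \code{eta}, \code{xi1}, \code{xi2}.
#' @export
expected_invariants <- function() {
  utils::read.csv(fixture_path("expected_invariants.csv"))
}

#' Published resolving-index table (expected values)
#'
#' @return Data frame with columns \code{drug}, \code{FRZI1}, \code{FRZI2},
#'   \code{SRZI}, \code{RHM}, \code{RF}.
#' @export
expected_indices <- function() {
  utils::read.csv(fixture_path("expected_indices.csv"))
}

#' Load all packaged drug records
#'
#' Each record bundles a drug's molecular graph, its physicochemical
#' properties and the expected invariant/index values. Record-level
#' invariants are checked at load time: the fixture graph's vertex and edge
#' counts must equal the expected table, and the expected indices must
#' satisfy RHM = RF + 2 SRZI.
#'
#' @return Named list of 10 records, each a list with elements \code{name},
#'   \code{graph}, \code{properties}, \code{expected_invariants},
#'   \code{expected_indices}.
#' @export
load_all_drugs <- function() {
  inv <- expected_invariants()
  idx <- expected_indices()
  prop <- drug_properties()
  out <- lapply(inv$drug, function(d) {
    g <- load_drug_graph(d)
    ei <- inv[inv$drug == d, ]
    if (g$n != ei$n_vertices || g$m != ei$n_edges) {
      stop(sprintf(
        "fixture-integrity error: %s graph has %d vertices / %d edges, expected %d / %d",
        d, g$n, g$m, ei$n_vertices, ei$n_edges), call. = FALSE)
    }
    ex <- idx[idx$drug == d, ]
    if (ex$RHM != ex$RF + 2L * ex$SRZI) {
      stop(sprintf("fixture-integrity error: RHM identity fails for %s", d),
           call. = FALSE)
    }
    list(
      name = d, graph = g,
      properties = prop[prop$drug == d, ],
      expected_invariants = graph_invariants_record(
        beta = ei$beta, eta = ei$eta, xi1 = ei$xi1, xi2 = ei$xi2,
        n_vertices = ei$n_vertices, n_edges = ei$n_edges),
      expected_indices = resolving_indices_record(
        frzi1 = ex$FRZI1, frzi2 = ex$FRZI2, srzi = ex$SRZI,
        rhm = ex$RHM, rf = ex$RF)
    )
  })
  names(out) <- inv$drug
  out
}
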