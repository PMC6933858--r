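#' Define a probe chemotype
#'
#' A probe spec ties a topology residue name to the probe's heavy atoms and
#' to the pharmacophore feature templates it contributes. Feature kinds come
#' from a closed vocabulary; each template anchors its feature sphere on a
#' named heavy atom or on the centroid of a named heavy-atom subset.
#'
#' @param probe_name Probe identifier, e.g. `"isopropanol"`.
#' @param resname Topology residue name identifying copies of this probe in
#'   the simulated system (CGenFF-style probe residues).
#' @param heavy_atoms Character vector of heavy-atom names (at least one).
#' @param features List of feature templates, each a list with elements
#'   `kind` (one of `"hbond_donor"`, `"hbond_acceptor"`, `"hydrophobic"`,
#'   `"aromatic"`, `"negative_ion"`, `"positive_ion"`) and `atoms` (heavy
#'   atom name(s); the feature is anchored at their centroid, which for a
#'   single name is the atom position itself).
#' @return An object of class `probe_spec`.
#' @export
#' @examples
#' probe_spec("isobutane", "IBUT", c("C1", "C2", "C3", "C4"),
#'            list(list(kind = "hydrophobic", atoms = c("C1", "C2", "C3", "C4"))))
probe_spec <- function(probe_name, resname, heavy_atoms, features = list()) {
  stopifnot(is.character(probe_name), length(probe_name) == 1L,
            is.character(resname), length(resname) == 1L)
  if (length(heavy_atoms) < 1L)
    stop("probe '", probe_name, "': at least one heavy atom required")
  for (ft in features) {
    if (!ft$kind %in% FEATURE_KINDS)
      stop("probe '", probe_name, "': unknown feature kind '", ft$kind, "'")
    bad <- setdiff(ft$atoms, heavy_atoms)
    if (length(bad))
      stop("probe '", probe_name, "': feature anchor atom(s) ",
           paste(bad, collapse = ", "), " not among heavy atoms")
  }
  structure(list(probe_name = probe_name, resname = toupper(resname),
                 heavy_atoms = heavy_atoms, features = features),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat("Probe spec:", x$probe_name, sprintf("(residue %s)\n", x$resname))
  cat("  heavy atoms:", paste(x$heavy_atoms, collapse = " "), "\n")
  for (ft in x$features)
    cat("  feature:", ft$kind, "@", paste(ft$atoms, collapse = "+"), "\n")
  invisible(x)
}

FEATURE_KINDS <- c("hbond_donor", "hbond_acceptor", "hydrophobic",
                   "aromatic", "negative_ion", "positive_ion")

#' Built-in probe set for druggability simulations
#'
#' Specs for the six standard drug-fragment probes: isopropanol, acetamide,
#' imidazole, acetate, isopropylamine and isobutane. Feature templates
#' follow standard chemotype assignments: hydroxyl/amide donors, carbonyl
#' and ring-nitrogen acceptors, alkyl hydrophobics, an aromatic imidazole
#' ring, a carboxylate negative center and an ammonium positive center.
#' Users may pass any subset, replace residue names, or append their own
#' [probe_spec()] objects.
#'
#' @return Named list of `probe_spec` objects keyed by probe name.
#' @export
default_probe_specs <- function() {
  specs <- list(
    probe_spec("isopropanol", "IPRO",
               c("C1", "C2", "C3", "O2"),
               list(list(kind = "hbond_donor", atoms = "O2"),
                    list(kind = "hydrophobic", atoms = c("C1", "C2", "C3")))),
    probe_spec("acetamide", "ACAM",
               c("CC", "CT", "O", "N"),
               list(list(kind = "hbond_donor", atoms = "N"),
                    list(kind = "hbond_acceptor", atoms = "O"))),
    probe_spec("imidazole", "IMID",
               c("CG", "ND1", "CD2", "CE1", "NE2"),
               list(list(kind = "aromatic",
                         atoms = c("CG", "ND1", "CD2", "CE1", "NE2")),
                    list(kind = "hbond_donor", atoms = "ND1"),
                    list(kind = "hbond_acceptor", atoms = "NE2"))),
    probe_spec("acetate", "ACET",
               c("C1", "C2", "O1", "O2"),
               list(list(kind = "negative_ion", atoms = c("C2", "O1", "O2")),
                    list(kind = "hbond_acceptor", atoms = "O1"))),
    probe_spec("isopropylamine", "IPAM",
               c("C1", "C2", "C3", "N"),
               list(list(kind = "positive_ion", atoms = "N"),
                    list(kind = "hbond_donor", atoms = "N"))),
    probe_spec("isobutane", "IBUT",
               c("C1", "C2", "C3", "C4"),
               list(list(kind = "hydrophobic",
                         atoms = c("C1", "C2", "C3", "C4"))))
  )
  names(specs) <- vapply(specs, `[[`, "", "probe_name")
  specs
}

# Residue-name -> spec lookup for a spec list.
spec_by_resname <- function(specs) {
  m <- specs
  names(m) <- vapply(specs, `[[`, "", "resname")
  m
}
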