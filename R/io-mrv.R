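# Best-effort reader for a subset of Marvin document (.mrv) XML, the format
# curly-arrow diagrams are deposited in. Only the chemistry needed by the
# similarity method is read; sketch metadata (coordinates, text boxes,
# styling) is ignored and reported in a warnings attribute.
#
# Accepted subset:
#   <cml><MDocument>
#     <MChemicalStruct><molecule molID="m1">
#       <atomArray atomID="a1 a2" elementType="O C" formalCharge="-1 0"/>
#         (or nested <atom id="a1" elementType="O" formalCharge="-1"/>)
#       <bondArray><bond id="b1" atomRefs2="a1 a2" order="1"/></bondArray>
#     </molecule></MChemicalStruct>
#     <MEFlow electrons="2">            (electrons optional, default 2)
#       <atomSetPoint atomRefs="m1.a1"/>            atom endpoint
#       <bondSetPoint bondRefs="b1"/>               existing-bond endpoint
#       <atomSetPoint atomRefs="m1.a1 m1.a2"/>      two atoms: incipient bond
#     </MEFlow>
#   </MDocument></cml>
#
# The first child of MEFlow is the arrow source (tail), the second the sink
# (tip). Bond orders 1/2/3 map to single/double/triple; "A" maps to the
# aromatic bond type, kept distinct from alternating single/double bonds (no
# kekulization, so equality never depends on a kekulization choice).

mrv_bond_order <- function(sym) {
  out <- c("1" = "single", "2" = "double", "3" = "triple",
           "A" = "aromatic")[sym]
  if (anyNA(out)) {
    stop("unsupported MRV bond order symbol '",
         paste(unique(sym[is.na(out)]), collapse = "','"), "'")
  }
  unname(out)
}

strip_mol_prefix <- function(refs) sub("^[^.]+\\.", "", refs)

mrv_endpoint <- function(node, atom_ids, bond_tab, incipient_ok) {
  nm <- xml2::xml_name(node)
  if (nm == "atomSetPoint") {
    refs <- strip_mol_prefix(strsplit(
      xml2::xml_attr(node, "atomRefs"), "\\s+")[[1]])
    idx <- match(refs, names(atom_ids))
    if (anyNA(idx)) {
      stop("MRV arrow endpoint references undeclared atom(s): ",
           paste(refs[is.na(idx)], collapse = ","))
    }
    ids <- unname(atom_ids[idx])
    if (length(ids) == 1L) return(arrow_atom(ids))
    if (length(ids) == 2L) {
      key <- paste(sort(ids), collapse = "-")
      if (key %in% bond_tab$key) return(arrow_bond(ids[1], ids[2]))
      if (incipient_ok) return(arrow_incipient(ids[1], ids[2]))
      stop("MRV arrow tail references atom pair (",
           paste(refs, collapse = ","), ") with no bond between them")
    }
    stop("MRV arrow endpoint must reference one or two atoms")
  }
  if (nm == "bondSetPoint") {
    ref <- strip_mol_prefix(xml2::xml_attr(node, "bondRefs"))
    i <- match(ref, bond_tab$id)
    if (is.na(i)) {
      stop("MRV arrow endpoint references undeclared bond '", ref, "'")
    }
    return(arrow_bond(bond_tab$a[i], bond_tab$b[i]))
  }
  stop("unsupported MRV arrow endpoint element <", nm, ">")
}

#' Parse one catalytic step from Marvin document (.mrv) XML
#'
#' Reads the documented subset (see the package vignette): one molecule
#' block with atom/bond declarations and one `MEFlow` element per curly
#' arrow. Unsupported sketch features are skipped; their element names are
#' returned in the `"warnings"` attribute.
#'
#' @param xml an MRV document: a file path, XML string or `xml2` document.
#' @param step_index index assigned to the resulting step (default 1).
#' @return a [catalytic_step()] with a character `"warnings"` attribute.
#' @export
parse_mrv_step <- function(xml, step_index = 1L) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  doc <- xml2::xml_ns_strip(doc)
  warnings <- character(0)

  mol <- xml2::xml_find_first(doc, ".//molecule")
  if (inherits(mol, "xml_missing")) stop("MRV document has no <molecule> block")

  arr <- xml2::xml_find_first(mol, ".//atomArray")
  if (inherits(arr, "xml_missing")) stop("MRV molecule has no <atomArray>")
  atom_nodes <- xml2::xml_find_all(arr, "./atom")
  if (length(atom_nodes) > 0L) {
    raw_ids <- xml2::xml_attr(atom_nodes, "id")
    elems <- xml2::xml_attr(atom_nodes, "elementType")
    charges <- xml2::xml_attr(atom_nodes, "formalCharge")
    charges[is.na(charges)] <- "0"
  } else {
    raw_ids <- strsplit(xml2::xml_attr(arr, "atomID"), "\\s+")[[1]]
    elems <- strsplit(xml2::xml_attr(arr, "elementType"), "\\s+")[[1]]
    fc <- xml2::xml_attr(arr, "formalCharge")
    charges <- if (is.na(fc)) rep("0", length(raw_ids)) else
      strsplit(fc, "\\s+")[[1]]
  }
  if (length(elems) != length(raw_ids) || length(charges) != length(raw_ids)) {
    stop("MRV atomArray attribute lengths disagree")
  }
  atom_ids <- stats::setNames(seq_along(raw_ids), raw_ids)
  atoms <- data.frame(atom_id = seq_along(raw_ids),
                      element = element_number(elems),
                      charge = as.integer(charges))

  bond_nodes <- xml2::xml_find_all(mol, ".//bondArray/bond")
  bond_tab <- data.frame(id = character(0), a = integer(0), b = integer(0),
                         order = character(0), key = character(0))
  if (length(bond_nodes) > 0L) {
    refs <- strsplit(xml2::xml_attr(bond_nodes, "atomRefs2"), "\\s+")
    a <- vapply(refs, function(r) {
      i <- match(strip_mol_prefix(r[1]), names(atom_ids))
      if (is.na(i)) stop("MRV bond references undeclared atom '", r[1], "'")
      unname(atom_ids[i])
    }, integer(1))
    b <- vapply(refs, function(r) {
      i <- match(strip_mol_prefix(r[2]), names(atom_ids))
      if (is.na(i)) stop("MRV bond references undeclared atom '", r[2], "'")
      unname(atom_ids[i])
    }, integer(1))
    bond_tab <- data.frame(
      id = xml2::xml_attr(bond_nodes, "id"),
      a = a, b = b,
      order = mrv_bond_order(xml2::xml_attr(bond_nodes, "order")),
      key = paste(pmin(a, b), pmax(a, b), sep = "-"))
  }

  flows <- xml2::xml_find_all(doc, ".//MEFlow")
  arrows <- lapply(flows, function(fl) {
    pts <- xml2::xml_children(fl)
    supported <- xml2::xml_name(pts) %in% c("atomSetPoint", "bondSetPoint")
    if (any(!supported)) {
      warnings <<- c(warnings, paste0("ignored MEFlow child <",
                                      xml2::xml_name(pts)[!supported], ">"))
      pts <- pts[supported]
    }
    if (length(pts) != 2L) {
      stop("MEFlow must have exactly one source and one sink endpoint")
    }
    el <- xml2::xml_attr(fl, "electrons")
    electrons <- if (is.na(el)) 2L else as.integer(el)
    curly_arrow(electrons,
                source = mrv_endpoint(pts[[1]], atom_ids, bond_tab,
                                      incipient_ok = FALSE),
                sink = mrv_endpoint(pts[[2]], atom_ids, bond_tab,
                                    incipient_ok = TRUE))
  })

  known <- c("MChemicalStruct", "MEFlow")
  extra <- setdiff(xml2::xml_name(
    xml2::xml_children(xml2::xml_find_first(doc, ".//MDocument"))), known)
  if (length(extra) > 0L) {
    warnings <- c(warnings, paste0("ignored MDocument element <", extra, ">"))
  }

  step <- catalytic_step(step_index,
                         site_state(atoms, if (nrow(bond_tab) > 0L) {
                           bond_tab[, c("a", "b", "order")]
                         } else NULL),
                         arrows)
  v <- validate_step(step, sprintf("step %d", step_index))
  if (length(v) > 0L) {
    stop("MRV step fails validation:\n  ", paste(v, collapse = "\n  "))
  }
  attr(step, "warnings") <- warnings
  step
}
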