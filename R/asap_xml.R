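# Read/write polygon annotations in the XML dialect of the ASAP
# histopathology slide viewer: root ASAP_Annotations, an Annotations list of
# Annotation elements (Name, Type = "Polygon", PartOfGroup, Color) each
# holding Coordinates of Coordinate{Order, X, Y}, plus an AnnotationGroups
# section naming the groups.

# exact decimal serialization so that write -> read round-trips vertices
num_str <- function(v) sprintf("%.17g", v)

#' Write an annotation document as ASAP-compatible XML
#'
#' @param doc an [annotation_document()].
#' @param path output XML path.
#' @param color polygon display color.
#' @return `path`, invisibly.
#' @export
write_asap_xml <- function(doc, path, color = "#F4FA58") {
  stopifnot(inherits(doc, "annotation_document"))
  root <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(root, "Annotations")
  for (p in doc$polygons) {
    ann <- xml2::xml_add_child(anns, "Annotation", Name = p$name,
                               Type = "Polygon", PartOfGroup = p$group,
                               Color = color)
    coords <- xml2::xml_add_child(ann, "Coordinates")
    for (r in seq_len(nrow(p$coords))) {
      xml2::xml_add_child(coords, "Coordinate",
                          Order = as.character(p$coords[r, "order"]),
                          X = num_str(p$coords[r, "x"]),
                          Y = num_str(p$coords[r, "y"]))
    }
  }
  groups <- xml2::xml_add_child(root, "AnnotationGroups")
  for (g in unique(vapply(doc$polygons, `[[`, character(1), "group"))) {
    gn <- xml2::xml_add_child(groups, "Group", Name = g,
                              PartOfGroup = "None", Color = "#64FE2E")
    xml2::xml_add_child(gn, "Attributes")
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read an ASAP XML annotation file
#'
#' Coordinates are returned exactly as stored (slide space); the
#' magnification factor is not part of the ASAP schema and defaults to 1.
#'
#' @param path XML file.
#' @param magnification_factor recorded on the returned document.
#' @return an [annotation_document()].
#' @export
read_asap_xml <- function(path, magnification_factor = 1) {
  xml <- xml2::read_xml(path)
  if (xml2::xml_name(xml) != "ASAP_Annotations") {
    stop("not an ASAP annotation file: root element is ",
         xml2::xml_name(xml))
  }
  polys <- lapply(xml2::xml_find_all(xml, ".//Annotation"), function(ann) {
    cs <- xml2::xml_find_all(ann, ".//Coordinate")
    ord <- as.integer(xml2::xml_attr(cs, "Order"))
    coords <- cbind(order = sort(ord),
                    x = as.numeric(xml2::xml_attr(cs, "X"))[order(ord)],
                    y = as.numeric(xml2::xml_attr(cs, "Y"))[order(ord)])
    list(name = xml2::xml_attr(ann, "Name"),
         group = xml2::xml_attr(ann, "PartOfGroup"),
         coords = coords)
  })
  annotation_document(polys, magnification_factor)
}
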