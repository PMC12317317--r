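# Edge-type alphabet of the collapsed RPI (regulatory + physical
# interaction) graph and the fixed orbit labelling of edge endpoints.
#
# Every node pair carries at most one labelled edge:
#   P  - physical only                     end orbits (1, 1)
#   R  - single regulatory edge            end orbits (2, 3), 2 = regulator
#   PR - physical + single regulatory      end orbits (4, 5), 4 = regulator
#   B  - bidirected regulatory (mutual)    end orbits (6, 6)
#   PB - physical + bidirected regulatory  end orbits (7, 7)
#
# Orbits 4 and 5 (physical edge with outgoing / incoming regulatory edge)
# are fixed by convention in the field; the remaining integer assignments
# are a catalog convention and all downstream counts are invariant to it.
# Orbit 0 marks a non-edge.

EDGE_TYPES <- c("P", "R", "PR", "B", "PB")

# end-orbit codes per type; for oriented types the regulator end is first
TYPE_END_ORBITS <- list(
  P  = c(1L, 1L),
  R  = c(2L, 3L),
  PR = c(4L, 5L),
  B  = c(6L, 6L),
  PB = c(7L, 7L)
)

# partner code: if x carries orbit o toward y, y carries PARTNER[o] toward x
PARTNER_ORBIT <- c(1L, 3L, 2L, 5L, 4L, 6L, 7L)

# endpoint codes implying a physical / regulatory component on the edge
PHYS_ORBITS <- c(1L, 4L, 5L, 7L)
REG_ORBITS  <- c(2L, 3L, 4L, 5L, 6L, 7L)

# the 8 admissible states of an ordered node pair, as (o_xy, o_yx)
PAIR_STATES <- list(
  c(0L, 0L), c(1L, 1L), c(2L, 3L), c(3L, 2L),
  c(4L, 5L), c(5L, 4L), c(6L, 6L), c(7L, 7L)
)

# unordered pair code lo*8 + hi (lo <= hi) -> edge type
TYPE_BY_PAIRCODE <- c(
  "9"  = "P",   # (1,1)
  "19" = "R",   # (2,3)
  "37" = "PR",  # (4,5)
  "54" = "B",   # (6,6)
  "63" = "PB"   # (7,7)
)

#' Edge type implied by a pair of endpoint orbit codes
#'
#' Maps the two endpoint orbit codes of a labelled edge (in either order)
#' to its edge type.
#'
#' @param o1,o2 Integer endpoint orbit codes in 1..7.
#' @return Character vector of edge types among `"P"`, `"R"`, `"PR"`,
#'   `"B"`, `"PB"`.
#' @examples
#' edge_type_of(2, 3)  # "R"
#' edge_type_of(5, 4)  # "PR"
#' @export
edge_type_of <- function(o1, o2) {
  code <- pmin(o1, o2) * 8L + pmax(o1, o2)
  ty <- TYPE_BY_PAIRCODE[as.character(code)]
  if (anyNA(ty)) {
    stop_internal("inconsistent endpoint orbit codes: ",
                  paste(o1[is.na(ty)], o2[is.na(ty)], sep = "/",
                        collapse = ", "))
  }
  unname(ty)
}
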