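#' State codings for the two behavioral characters
#'
#' Retreat construction method: opportunist (taxa inhabiting existing
#' spaces) = 0, obligate burrower = 1, nest-builder (short silken nests
#' attached to the substrate) = 2. Retreat-entrance type: web (sheet,
#' funnel or curtain at the entrance) = 0, open = 1, turret = 2,
#' collar = 3, trapdoor (hinged door) = 4, purse (camouflaged extension
#' of the burrow lining) = 5.
#'
#' @return named integer vector of state codes.
#' @name behavior-states
#' @export
retreatStates <- function() {
  c(opportunist = 0L, obligate_burrower = 1L, nest_builder = 2L)
}

#' @rdname behavior-states
#' @export
entranceStates <- function() {
  c(web = 0L, open = 1L, turret = 2L, collar = 3L, trapdoor = 4L, purse = 5L)
}

#' Binary trait with ambiguity and missingness
#'
#' A per-taxon binary variable taking values in `{"0", "1", "ambiguous",
#' "missing"}`. `"ambiguous"` arises only when a polymorphic source cell
#' spans both sides of a binarization; `"missing"` propagates from
#' missing source cells.
#'
#' @param name trait name.
#' @param values named character vector over the four tokens.
#' @return object of class `binaryTrait`.
#' @export
binaryTrait <- function(name, values) {
  stopifnot(is.character(values), !is.null(names(values)))
  bad <- setdiff(unique(values), c("0", "1", "ambiguous", "missing"))
  if (length(bad)) stop("invalid binary trait values: ", paste(bad, collapse = ", "))
  structure(list(name = name, values = values), class = "binaryTrait")
}

#' @export
print.binaryTrait <- function(x, ...) {
  tab <- table(factor(x$values, levels = c("0", "1", "ambiguous", "missing")))
  cat("binaryTrait '", x$name, "' over ", length(x$values), " taxa: ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Binarize a state-set character
#'
#' Maps each taxon's state set onto `1` (set wholly inside `oneStates`),
#' `0` (wholly outside), `ambiguous` (states on both sides), or
#' `missing` (empty set).
#'
#' @param stateSets named list of integer state sets (e.g. from
#'   [charStates()]).
#' @param oneStates integer states forming the "1" side.
#' @param name trait name.
#' @return a [binaryTrait()].
#' @export
binarizeStates <- function(stateSets, oneStates, name) {
  vals <- vapply(stateSets, function(s) {
    if (!length(s)) return("missing")
    inside <- s %in% oneStates
    if (all(inside)) "1" else if (!any(inside)) "0" else "ambiguous"
  }, character(1))
  binaryTrait(name, vals)
}

#' Derive the five key binary behaviors
#'
#' From the two multistate behavioral characters (retreat construction
#' method, 3 states; retreat-entrance type, 6 states) derives the five
#' behaviors screened for morphological correlates:
#'
#' * `web_building` — entrance type is a web;
#' * `opportunist` — retreat method is opportunistic;
#' * `burrowing` — retreat method is obligate burrowing;
#' * `entrance_modification` — entrance bears a purse, collar, turret or
#'   trapdoor;
#' * `trapdoor` — entrance bears a hinged trapdoor.
#'
#' Polymorphic cells spanning both sides of a binarization yield
#' `ambiguous`; missing cells yield `missing`.
#'
#' @param cm a `charMatrix` containing the two behavioral characters.
#' @param retreatChar,entranceChar character ids of the retreat-method
#'   and entrance-type characters.
#' @return named list of five [binaryTrait()] objects.
#' @examples
#' cells <- matrix(list(1L, 4L, 0L, 0L, c(1L, 4L), 1L), 3, 2,
#'                 dimnames = list(c("Euoplos", "Namirea", "Arbanitis"), NULL))
#' meta <- data.frame(id = c("retreat_method", "entrance_type"),
#'                    n_states = c(3L, 6L), ordered = FALSE)
#' cm <- characterMatrix(cells, meta = meta)
#' deriveBehaviors(cm)$trapdoor$values
#' @export
deriveBehaviors <- function(cm, retreatChar = "retreat_method",
                            entranceChar = "entrance_type") {
  stopifnot(inherits(cm, "charMatrix"))
  if (!all(c(retreatChar, entranceChar) %in% cm$meta$id))
    stop("behavioral characters not found in matrix: ",
         retreatChar, ", ", entranceChar)
  kR <- cm$meta$n_states[match(retreatChar, cm$meta$id)]
  kE <- cm$meta$n_states[match(entranceChar, cm$meta$id)]
  if (kR > 3L || kE > 6L)
    stop("unexpected state space for behavioral characters (retreat <= 3, entrance <= 6)")
  retreat <- charStates(cm, retreatChar)
  entrance <- charStates(cm, entranceChar)
  rs <- retreatStates(); es <- entranceStates()
  list(
    web_building = binarizeStates(entrance, es[["web"]], "web_building"),
    opportunist = binarizeStates(retreat, rs[["opportunist"]], "opportunist"),
    burrowing = binarizeStates(retreat, rs[["obligate_burrower"]], "burrowing"),
    entrance_modification = binarizeStates(
      entrance, es[c("purse", "collar", "turret", "trapdoor")],
      "entrance_modification"),
    trapdoor = binarizeStates(entrance, es[["trapdoor"]], "trapdoor")
  )
}

# binary trait -> integer vector with NA for ambiguous/missing
traitAsNumeric <- function(trait) {
  v <- suppressWarnings(as.integer(trait$values))
  stats::setNames(v, names(trait$values))
}

# binary trait -> per-taxon state sets over {0,1} (ambiguous = both,
# missing = both); used when feeding likelihood methods
traitAsStateSets <- function(trait) {
  lapply(stats::setNames(trait$values, names(trait$values)), function(v)
    switch(v, "0" = 0L, "1" = 1L, c(0L, 1L)))
}
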