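## Pedigree construction, validation, ordering, tracing.

.unknown <- function(x) is.na(x) | x == "" | x == "0"

#' Construct a validated, topologically ordered pedigree
#'
#' Animals are reordered (stably) so that every parent precedes its
#' offspring; unknown parents may be coded \code{NA}, the empty string or
#' \code{"0"}. A parent that never appears as an animal is added as a
#' founder with a warning.
#'
#' @param animal character (or coercible) vector of animal ids.
#' @param sire,dam parent ids, same length as \code{animal}.
#' @return a [Pedigree-class]
#' @examples
#' ped <- Pedigree(c("C", "A", "B"), c("A", NA, NA), c("B", NA, NA))
#' animalIds(ped)   # A and B placed before C
#' @export
Pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have the same length")
  if (anyDuplicated(animal))
    stop("duplicate animal id: ", animal[duplicated(animal)][1L])
  sire[.unknown(sire)] <- NA_character_
  dam[.unknown(dam)] <- NA_character_
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("cycle detected in pedigree: ",
         animal[which(!is.na(sire) & sire == animal |
                      !is.na(dam) & dam == animal)][1L],
         " -> ", animal[which(!is.na(sire) & sire == animal |
                              !is.na(dam) & dam == animal)][1L])
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  extra <- setdiff(parents, animal)
  if (length(extra)) {
    warning(length(extra), " parent(s) not listed as animals were added ",
            "as founders: ", paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }
  n <- length(animal)
  code <- seq_len(n)
  names(code) <- animal
  si <- unname(code[sire])   # NA for unknown
  di <- unname(code[dam])

  ## Kahn topological sort (stable: ties broken by input position)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(si[j], di[j])) {
      if (!is.na(p)) {
        indeg[j] <- indeg[j] + 1L
        kids[[p]] <- c(kids[[p]], j)
      }
    }
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  indeg2 <- indeg
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg2[k] <- indeg2[k] - 1L
      if (indeg2[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) < n) {
    ## every remaining animal lies on or above a cycle; walk one out
    left <- setdiff(seq_len(n), order)
    v <- left[1L]; path <- v
    repeat {
      p <- if (!is.na(si[v]) && si[v] %in% left) si[v] else di[v]
      if (p %in% path) {
        cyc <- c(path[which(path == p):length(path)], p)
        stop("cycle detected in pedigree: ",
             paste(animal[cyc], collapse = " -> "))
      }
      path <- c(path, p); v <- p
    }
  }
  pos <- integer(n); pos[order] <- seq_len(n)
  id2 <- animal[order]
  s2 <- ifelse(is.na(si[order]), NA_integer_, pos[si[order]])
  d2 <- ifelse(is.na(di[order]), NA_integer_, pos[di[order]])
  new("Pedigree", id = id2, sire = as.integer(s2), dam = as.integer(d2),
      depth = .genDepth(as.integer(s2), as.integer(d2)))
}

## minimum number of meioses above the closest base (childless) animal
.genDepth <- function(sire, dam) {
  n <- length(sire)
  if (!n) return(integer(0))
  isParent <- logical(n)
  isParent[stats::na.omit(c(sire, dam))] <- TRUE
  depth <- ifelse(isParent, NA_integer_, 0L)
  ## sweep offspring -> parents; order guarantees offspring index > parent
  for (j in n:1) {
    if (is.na(depth[j])) next
    for (p in c(sire[j], dam[j])) {
      if (!is.na(p) && (is.na(depth[p]) || depth[p] > depth[j] + 1L))
        depth[p] <- depth[j] + 1L
    }
  }
  ## isolated founders that are also childless already have depth 0
  depth[is.na(depth)] <- 0L
  as.integer(depth)
}

#' Read a pedigree from CSV
#'
#' Expects a header and three columns \code{animal,sire,dam}; unknown
#' parents are the empty string or \code{"0"}.
#'
#' @param path file path.
#' @return a [Pedigree-class]
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns animal, sire, dam")
  Pedigree(df$animal, df$sire, df$dam)
}

#' Write a pedigree to CSV
#' @param ped a [Pedigree-class]
#' @param path file path.
#' @export
writePedigree <- function(ped, path) {
  df <- data.frame(animal = ped@id,
                   sire = ifelse(is.na(ped@sire), "", ped@id[ped@sire]),
                   dam = ifelse(is.na(ped@dam), "", ped@id[ped@dam]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trace a pedigree back a fixed number of generations
#'
#' Returns the sub-pedigree holding the base animals plus every ancestor
#' reachable in at most \code{max_generations} meioses; parents lying beyond
#' the horizon are recoded unknown.
#'
#' @param ped a [Pedigree-class]
#' @param base character vector of base animal ids.
#' @param max_generations non-negative integer horizon.
#' @return a [Pedigree-class]
#' @export
traceBack <- function(ped, base, max_generations) {
  stopifnot(is(ped, "Pedigree"), max_generations >= 0)
  miss <- setdiff(base, ped@id)
  if (length(miss))
    stop("base animal(s) not in pedigree: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  n <- length(ped@id)
  dist <- rep(NA_integer_, n)
  dist[match(base, ped@id)] <- 0L
  ## ancestors have smaller indices; sweep from high to low
  for (j in n:1) {
    if (is.na(dist[j]) || dist[j] >= max_generations) next
    for (p in c(ped@sire[j], ped@dam[j]))
      if (!is.na(p) && (is.na(dist[p]) || dist[p] > dist[j] + 1L))
        dist[p] <- dist[j] + 1L
  }
  keep <- which(!is.na(dist))
  inKeep <- logical(n); inKeep[keep] <- TRUE
  sub <- function(p) {
    if (is.na(p) || !inKeep[p]) NA_character_ else ped@id[p]
  }
  sire <- vapply(keep, function(j) sub(ped@sire[j]), character(1))
  dam <- vapply(keep, function(j) sub(ped@dam[j]), character(1))
  Pedigree(ped@id[keep], sire, dam)
}
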