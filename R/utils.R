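# internal helpers shared across modules

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

transitionPartner <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}

isTransitionPair <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) |
    (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

# canonical empty variant table
emptyVariants <- function() {
  data.frame(position = integer(), kind = character(), ref = character(),
             alt = character(), insert_index = integer(),
             label = character(), stringsAsFactors = FALSE)
}

# build a variant table from parallel vectors, deriving canonical labels
makeVariants <- function(position, kind, ref, alt, insert_index = 0L) {
  n <- length(position)
  if (n == 0L) return(emptyVariants())
  insert_index <- rep_len(as.integer(insert_index), n)
  label <- character(n)
  for (i in seq_len(n)) {
    label[i] <- switch(kind[i],
      transition = as.character(position[i]),
      transversion = paste0(position[i], alt[i]),
      insertion = paste0(position[i], ".", insert_index[i], alt[i]),
      deletion = paste0(position[i], "d"),
      stop("unknown variant kind: ", kind[i]))
  }
  out <- data.frame(position = as.integer(position), kind = kind,
                    ref = ref, alt = alt, insert_index = insert_index,
                    label = label, stringsAsFactors = FALSE)
  sortVariants(out)
}

sortVariants <- function(v) {
  o <- order(v$position, v$insert_index,
             match(v$kind, c("transition", "transversion",
                             "insertion", "deletion")))
  v <- v[o, , drop = FALSE]
  rownames(v) <- NULL
  v
}

# parent lookup vector (index = node, value = parent node, root -> NA)
parentVector <- function(tree) {
  nNode <- max(tree@edge)
  p <- rep(NA_integer_, nNode)
  p[tree@edge[, 2]] <- tree@edge[, 1]
  p
}

rootNode <- function(tree) tree@nTips + 1L

# tips in the subtree rooted at `node`
tipsUnder <- function(tree, node) {
  n <- tree@nTips
  if (node <= n) return(node)
  kids <- tree@edge[tree@edge[, 1] == node, 2]
  unlist(lapply(kids, tipsUnder, tree = tree))
}

# edge indices on the path root -> node
pathEdges <- function(tree, node) {
  p <- parentVector(tree)
  childOf <- tree@edge[, 2]
  out <- integer()
  while (!is.na(p[node])) {
    out <- c(out, which(childOf == node))
    node <- p[node]
  }
  rev(out)
}

# most recent common ancestor of a set of tips
mrcaNode <- function(tree, tips) {
  if (length(tips) == 1L) return(tips)
  p <- parentVector(tree)
  anc <- function(v) {
    out <- v
    while (!is.na(p[v])) { v <- p[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(tips, anc))
  common[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
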