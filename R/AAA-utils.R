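DNA_BASES4 <- c("A", "C", "G", "T")

## integer coding A=1 C=2 G=3 T=4; complement is 5 - code
dnaToInt <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], DNA_BASES4)
  v
}

intToDna <- function(v) paste(DNA_BASES4[v], collapse = "")

## character matrix (n x L) of A/C/G/T -> integer matrix
seqMatrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(match(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                    DNA_BASES4),
              nrow = n, ncol = L, byrow = TRUE)
  m
}

## Evaluate expr under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Deterministic child seed in [1, 2^31 - 2] from a master seed and tags.
## Multiplications stay below 2^53 so double arithmetic is exact.
childSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (t in tags) {
    h <- (h * 48271 + as.double(t) + 1) %% 2147483563
  }
  as.integer(h %% 2147483562) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Single-base feature items ------------------------------------------------
## item code = (position - 1) * 4 + base, base in 1..4 (A,C,G,T)

itemCode <- function(base, position) (position - 1L) * 4L + base

itemPosition <- function(code) (code - 1L) %/% 4L + 1L

itemBase <- function(code) (code - 1L) %% 4L + 1L

#' Render single-base feature items as labels
#'
#' An item is a single-base feature: a nucleotide base at a 1-based motif
#' position, rendered as e.g. `"C2"` (base C at position 2).
#'
#' @param code integer item code(s) as used internally by the mining
#'   functions.
#' @return character vector of labels such as `"C2"`.
#' @export
itemLabel <- function(code) {
  paste0(DNA_BASES4[itemBase(code)], itemPosition(code))
}

## parse "C2" -> code
parseItemLabel <- function(label) {
  base <- match(substr(label, 1L, 1L), DNA_BASES4)
  pos <- as.integer(substring(label, 2L))
  if (anyNA(base) || anyNA(pos)) {
    stop("malformed item label: ", paste(label[is.na(base) | is.na(pos)],
                                         collapse = ", "))
  }
  itemCode(base, pos)
}

## canonical feature/itemset id: items sorted by position, ":"-joined
itemsetId <- function(codes) {
  codes <- sort(as.integer(codes))
  paste(itemLabel(codes), collapse = ":")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
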