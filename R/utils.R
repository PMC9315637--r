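#' @keywords internal
"_PACKAGE"

#' @importFrom stats median pbinom phyper p.adjust quantile rbinom runif setNames
#' @importFrom utils read.delim write.table combn head
NULL

# half-up rounding to integer; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

# recognised toxicity labels, from most to least hepatotoxic
TOXICITY_CLASSES <- c("very_toxic", "toxic", "non_toxic", "safe")

# labels counted as DILI-positive when a binary split is needed
DILI_CLASSES <- c("very_toxic", "toxic")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

stop_dilinet <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "dilinet_error")))
}

# canonical key for an unordered node pair
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
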