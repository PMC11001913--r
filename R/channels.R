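#' Canonical mutation channel sets
#'
#' Channel label vectors for the three catalog types handled by the
#' refitting machinery: the 96 trinucleotide single-base-substitution
#' channels (`SBS96`), the 83 COSMIC-style small indel channels (`ID83`)
#' and the 32 rearrangement channels (`SV32`: clustered / non-clustered
#' by type and size, plus translocations).
#'
#' @return A character vector of channel labels in canonical order.
#' @examples
#' length(sbs96_channels())
#' head(id83_channels())
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(p, q) paste0(p, "[", s, "]", q))))
  }))
}

#' @rdname sbs96_channels
#' @export
id83_channels <- function() {
  reps <- 0:5
  c(
    paste0("1:Del:C:", reps), paste0("1:Del:T:", reps),
    paste0("1:Ins:C:", reps), paste0("1:Ins:T:", reps),
    paste0("2:Del:R:", reps), paste0("3:Del:R:", reps),
    paste0("4:Del:R:", reps), paste0("5:Del:R:", reps),
    paste0("2:Ins:R:", reps), paste0("3:Ins:R:", reps),
    paste0("4:Ins:R:", reps), paste0("5:Ins:R:", reps),
    "2:Del:M:1", paste0("3:Del:M:", 1:2), paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

#' @rdname sbs96_channels
#' @export
sv32_channels <- function() {
  sizes <- c("1-10Kb", "10-100Kb", "100Kb-1Mb", "1Mb-10Mb", ">10Mb")
  types <- c("del", "tds", "inv")
  one <- function(prefix) {
    c(as.vector(t(outer(types, sizes, function(t, s) paste(prefix, t, s, sep = ":")))),
      paste(prefix, "trans", sep = ":"))
  }
  c(one("clustered"), one("non-clustered"))
}

channel_labels <- function(channel_set) {
  switch(channel_set,
    SBS96 = sbs96_channels(),
    ID83 = id83_channels(),
    SV32 = sv32_channels(),
    abort(paste0("unknown channel set: ", channel_set))
  )
}

match_channel_set <- function(channel_set) {
  if (!is.character(channel_set) || length(channel_set) != 1 ||
      !channel_set %in% c("SBS96", "ID83", "SV32")) {
    abort("channel_set must be one of 'SBS96', 'ID83', 'SV32'")
  }
  channel_set
}
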