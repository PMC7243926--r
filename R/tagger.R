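#' Reference part-of-speech tagger
#'
#' A compact, deterministic Penn-Treebank tagger built from a closed-class
#' lexicon plus suffix rules. It is the package's reference configuration for
#' the POS-weighted retrieval model; any function mapping a token vector to a
#' tag vector can be plugged in instead via the `tagger` argument of
#' [pos_tag()]. Like the general-English tagger whose behaviour the model was
#' analyzed with, it tags the bare imperative "search" as NN (queries are not
#' complete sentences), and unknown words default to NN.
#'
#' @param tokens Character vector of tokens (any case).
#' @return Character vector of Penn tags, one per token.
#' @export
default_pos_tagger <- function(tokens) {
  vapply(tokens, tag_one_token, character(1), USE.NAMES = FALSE)
}

tagger_lexicon <- c(
  # determiners / conjunctions / prepositions / particles
  the = "DT", a = "DT", an = "DT", all = "DT", this = "DT", that = "DT",
  these = "DT", those = "DT", each = "DT", every = "DT", some = "DT",
  any = "DT", no = "DT",
  and = "CC", or = "CC", but = "CC", nor = "CC",
  of = "IN", `in` = "IN", on = "IN", at = "IN", by = "IN", `for` = "IN",
  with = "IN", from = "IN", into = "IN", across = "IN", between = "IN",
  during = "IN", about = "IN", over = "IN", under = "IN", within = "IN",
  through = "IN", after = "IN", before = "IN", against = "IN", as = "IN",
  to = "TO",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB", been = "VBN",
  being = "VBG", has = "VBZ", have = "VBP", had = "VBD", do = "VBP",
  does = "VBZ", did = "VBD", can = "MD", could = "MD", will = "MD",
  would = "MD", may = "MD", might = "MD", should = "MD", must = "MD",
  not = "RB", also = "RB", very = "RB", more = "RBR", most = "RBS",
  i = "PRP", we = "PRP", it = "PRP", they = "PRP", he = "PRP", she = "PRP",
  # verbs commonly heading retrieval queries
  find = "VB", show = "VB", list = "VB", get = "VB", give = "VB",
  identify = "VB", retrieve = "VB", locate = "VB",
  # frequent irregular forms / words the suffix rules would miss
  data = "NNS", children = "NNS", women = "NNS", men = "NNS", mice = "NNS",
  criteria = "NNS", bacteria = "NNS", media = "NNS", series = "NN",
  found = "VBN", given = "VBN", shown = "VBN", known = "VBN", seen = "VBN",
  made = "VBN", done = "VBN", used = "VBN",
  # common adjectives without a marking suffix
  obese = "JJ", new = "JJ", old = "JJ", high = "JJ", low = "JJ",
  large = "JJ", small = "JJ", early = "JJ", late = "JJ", severe = "JJ",
  mild = "JJ", acute = "JJ", benign = "JJ", malignant = "JJ", male = "JJ",
  female = "JJ", adult = "JJ", same = "JJ", different = "JJ", common = "JJ")

tag_one_token <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) return("NN")
  low <- tolower(tok)
  if (grepl("^[0-9]+([.,][0-9]+)*$", low)) return("CD")
  hit <- tagger_lexicon[low]
  if (!is.na(hit)) return(unname(hit))
  # mixed-case input: capitalized or abbreviated tokens are proper nouns
  if (grepl("[A-Z]", tok) && (grepl("\\.$", tok) || grepl("^[A-Z]", tok)))
    return("NNP")
  n <- nchar(low)
  ends <- function(suf) n > nchar(suf) + 1L && endsWith(low, suf)
  if (ends("ing")) return("VBG")
  if (ends("ed")) return("VBN")
  if (ends("ly")) return("RB")
  if (ends("ous") || ends("ful") || ends("ive") || ends("ble") ||
      ends("ish") || ends("ic") || ends("ical") || ends("ary") ||
      ends("al")) return("JJ")
  if (ends("tion") || ends("sion") || ends("ment") || ends("ness") ||
      ends("ity") || ends("ism") || ends("ogy")) return("NN")
  if (endsWith(low, "s") && n > 3L && !endsWith(low, "ss") &&
      !endsWith(low, "us") && !endsWith(low, "is")) return("NNS")
  "NN"
}

#' Tag tokens with Penn-Treebank part-of-speech classes
#'
#' @param tokens Non-empty character vector.
#' @param tagger Optional replacement tagger `function(tokens) -> tags`.
#' @return Character vector of tags, one per token.
#' @export
pos_tag <- function(tokens, tagger = NULL) {
  if (length(tokens) == 0L) stop("pos_tag requires a non-empty token vector")
  f <- if (is.null(tagger)) default_pos_tagger else tagger
  tags <- f(tokens)
  if (length(tags) != length(tokens))
    stop("tagger returned ", length(tags), " tags for ", length(tokens),
         " tokens")
  as.character(tags)
}
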