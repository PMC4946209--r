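#' English stop words with forced zero weight
#'
#' Common English function words that receive weight zero in every field
#' index regardless of their document frequency, together with
#' punctuation-only tokens (which the tokenizer drops anyway). The list is
#' deliberately short and fixed so that results are reproducible.
#'
#' @return character vector of lowercase stop words.
#' @export
stopwords_en <- function() {
  c(
    "a", "about", "above", "after", "again", "all", "also", "an", "and",
    "any", "are", "as", "at", "be", "because", "been", "before", "being",
    "below", "between", "both", "but", "by", "can", "could", "did", "do",
    "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
    "itself", "just", "more", "most", "my", "no", "nor", "not", "now", "of",
    "off", "on", "once", "only", "or", "other", "our", "out", "over", "own",
    "per", "same", "she", "should", "so", "some", "such", "than", "that",
    "the", "their", "theirs", "them", "then", "there", "these", "they",
    "this", "those", "through", "to", "too", "under", "until", "up", "upon",
    "very", "was", "we", "were", "what", "when", "where", "which", "while",
    "who", "whom", "why", "will", "with", "would", "you", "your", "yours"
  )
}
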