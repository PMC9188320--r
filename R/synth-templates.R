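# Sentence templates for the synthetic report generator.
#
# Each template is a character vector of word tokens. "{V}" marks the slot
# for the gold value (AHI or SaO2 depending on the template family); "{D}"
# marks a distractor-value slot whose value is drawn from the named pool.
# Punctuation stays attached to tokens the way word-level OCR emits it
# ("(AHI)", "19.5.", "87,"), because the downstream candidate regex operates
# on whole OCR words.

ahi_templates <- function() {
  list(
    c("The", "total", "APNEA/HYPOPNEA", "INDEX", "(AHI)", "was", "{V}."),
    c("Overall", "AHI", "was", "{V}", "events", "per", "hour", "of", "sleep"),
    c("The", "apnea", "hypopnea", "index", "(AHI)", "for", "the", "entire",
      "night", "was", "{V}"),
    c("This", "yields", "an", "overall", "AHI", "of", "{V}", "by", "AASM",
      "criteria")
  )
}

sao2_templates <- function() {
  list(
    c("The", "lowest", "desaturation", "was", "{V},", "with", "a", "mean",
      "value", "of", "{D:percent}."),
    c("Minimum", "oxygen", "saturation", "(SaO2)", "was", "{V}%"),
    c("The", "oxygen", "saturation", "nadir", "was", "{V}", "percent"),
    c("Oxygen", "saturation", "fell", "to", "a", "minimum", "of", "{V}",
      "during", "REM", "sleep")
  )
}

distractor_templates <- function() {
  list(
    c("The", "patient", "also", "had", "{D:count}", "respiratory", "event",
      "related", "arousals", "(RERA)"),
    c("A", "total", "of", "{D:count}", "hypopneas", "met", "the", "AASM",
      "Version", "II", "scoring", "rule"),
    c("while", "{D:count}", "met", "the", "Medicare", "scoring", "rule"),
    c("Total", "sleep", "time", "was", "{D:duration}", "minutes", "with",
      "a", "sleep", "efficiency", "of", "{D:percent}%"),
    c("The", "patient", "spent", "{D:duration}", "minutes", "in", "REM",
      "sleep"),
    c("Mean", "oxygen", "saturation", "during", "sleep", "was",
      "{D:percent}"),
    c("Versus", "a", "non-REM", "AHI", "of", "{D:rate}."),
    c("The", "respiratory", "disturbance", "index", "was", "{D:rate}",
      "in", "the", "supine", "position"),
    c("Periodic", "limb", "movements", "occurred", "{D:rate}", "times",
      "per", "hour"),
    c("Heart", "rate", "ranged", "from", "{D:count}", "to", "{D:count}",
      "beats", "per", "minute"),
    c("Snoring", "was", "noted", "during", "{D:percent}", "percent", "of",
      "the", "recording"),
    c("Sleep", "latency", "was", "{D:duration}", "minutes", "and", "REM",
      "latency", "was", "{D:duration}", "minutes")
  )
}

prose_templates <- function() {
  list(
    c("The", "patient", "tolerated", "the", "study", "well", "and", "slept",
      "primarily", "in", "the", "supine", "position"),
    c("Sleep", "architecture", "showed", "reduced", "slow", "wave", "sleep",
      "consistent", "with", "fragmentation"),
    c("CPAP", "titration", "is", "recommended", "and", "follow", "up", "was",
      "arranged", "with", "the", "sleep", "clinic"),
    c("The", "study", "was", "performed", "overnight", "in", "the", "sleep",
      "laboratory", "with", "standard", "montage"),
    c("Interpretation", "was", "provided", "by", "the", "attending",
      "sleep", "physician"),
    c("Findings", "are", "consistent", "with", "obstructive", "sleep",
      "apnea", "of", "moderate", "severity")
  )
}

# Template pair used in text-ambiguous mode: gold value and decoy distractors
# share the identical sentence so word context alone cannot separate them and
# layout must carry the signal.
ambiguous_template <- function(value_class) {
  if (value_class == "ahi") {
    c("The", "recorded", "index", "value", "for", "this", "study", "was",
      "{V}")
  } else {
    c("The", "recorded", "saturation", "value", "for", "this", "study",
      "was", "{V}")
  }
}

phi_first_names <- function() {
  c("John", "Mary", "James", "Patricia", "Robert", "Jennifer", "Michael",
    "Linda", "William", "Elizabeth", "David", "Barbara", "Richard", "Susan",
    "Joseph", "Jessica", "Thomas", "Sarah", "Charles", "Karen")
}

phi_last_names <- function() {
  c("Smith", "Johnson", "Williams", "Brown", "Jones", "Garcia", "Miller",
    "Davis", "Rodriguez", "Martinez", "Hernandez", "Lopez", "Gonzalez",
    "Wilson", "Anderson", "Taylor", "Thomas", "Moore", "Jackson", "Martin")
}
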