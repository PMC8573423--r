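# Host-information extraction rules.
# A non-empty `host` qualifier always counts as host information.
# Failing that, `isolation_source` is matched against isolation_patterns,
# then `title` and `note` against title_patterns; the first capture group
# of the first matching pattern is recorded as the host name.
isolation_patterns:
  - "gut content[s]? of (?:the )?([A-Za-z][A-Za-z ]*)"
  - "isolated from (?:the )?([A-Za-z][A-Za-z ]*)"
  - "swab(?: sample)?s? (?:of|from) (?:the )?([A-Za-z][A-Za-z ]*)"
  - "tissue[s]? (?:of|from) (?:the )?([A-Za-z][A-Za-z ]*)"
  - "infect(?:ed|ing) ([A-Za-z][A-Za-z ]*)"
title_patterns:
  - "parasite of (?:the )?(?:[a-z ]+, )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"
  - "parasitizing (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"
  - "infecting (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"
  - "isolated from (?:the )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"
  - "associated with (?:the )?(?:[a-z]+, )?([A-Z][A-Za-z]*(?: [a-z.]+)?)"
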