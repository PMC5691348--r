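# Slot name -> reader-facing change category used in rendered digests.
# Slots not listed here fall back to the lowercased slot name.
COMMENT: textual summary
GO-TERMS: GO term annotations
REGULATED-BY: regulation
REGULATED-ENTITY: regulation
CATALYZES: enzymatic activity
REACTION: enzymatic activity
REACTION-LIST: pathway structure
CITATIONS: citations
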