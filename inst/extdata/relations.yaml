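# Interest-closure relation sets.  Each closure type lists:
#   forward: follow <slot> from members whose classes intersect <classes>
#   reverse: add objects of <classes> whose <slot> names a member
#            (anchor_only: only the anchor counts as a hit)
# Traversal runs these to a fixed point; objects reached through a slot
# that has no rule of its own (pathways in a gene closure, compounds in a
# pathway closure) are included as members but not expanded further.
gene:
  forward:
    - classes: [GENE]
      slot: PRODUCT
    - classes: [PROTEIN, COMPLEX]
      slot: COMPONENT-OF
    - classes: [PROTEIN, COMPLEX]
      slot: CATALYZES
    - classes: [ENZYMATIC-REACTION]
      slot: REACTION
    - classes: [REACTION]
      slot: IN-PATHWAY
  reverse:
    - classes: [REGULATION]
      slot: REGULATED-ENTITY
    - classes: [TRANSCRIPTION-UNIT]
      slot: GENES
      anchor_only: true
pathway:
  forward:
    - classes: [PATHWAY]
      slot: REACTION-LIST
    - classes: [REACTION]
      slot: LEFT
    - classes: [REACTION]
      slot: RIGHT
    - classes: [COMPLEX]
      slot: COMPONENTS
    - classes: [PROTEIN]
      slot: GENE
  reverse:
    - classes: [ENZYMATIC-REACTION]
      slot: REACTION
    - classes: [PROTEIN, COMPLEX]
      slot: CATALYZES
    - classes: [REGULATION]
      slot: REGULATED-ENTITY
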