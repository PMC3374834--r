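# Sponsor-class keyword dictionary.
#
# Classes: hos (hospitals & clinics), edu (research/educational
# institutions), com (for-profit companies), gov (national and government
# organisations), col (collaborations: associations, networks, consortia).
# Priority is a total order, highest first: a name matching keywords of two
# classes is assigned the higher-priority one, so "University Hospital" is
# hos, not edu. Keywords are matched case-insensitively at word boundaries
# on the normalised sponsor name; diacritics are significant (multilingual
# entries are listed explicitly). A trailing "." in a keyword also matches
# when the dotless form ends the name ("Acme Corp" ~ "corp.").
#
# The keyword sets are a reconstruction: registry sponsors are filed in many
# languages and no canonical dictionary exists. Users are expected to refine
# this file for their own corpora; it is data, not code.
priority: [hos, edu, com, gov, col]
fallback:
  Industry: com
  NIH: gov
  U.S. Fed: gov
  Other: unclassified
classes:
  hos:
    keywords:
      - hospital
      - hospitals
      - "hôpital"
      - "hôpitaux"
      - hospices
      - clinic
      - clinics
      - klinik
      - kliniken
      - klinikum
      - ospedale
      - sjukhus
      - sjukhuset
      - ziekenhuis
      - medical center
      - medical centre
      - health center
      - health centre
      - infirmary
      - cancer center
      - cancer centre
  edu:
    keywords:
      - university
      - universities
      - "università"
      - "universität"
      - "université"
      - universidad
      - universidade
      - universiteit
      - universitet
      - college
      - school of medicine
      - medical school
      - academy
      - academia
      - research institute
      - research center
      - research centre
      - polytechnic
  com:
    keywords:
      - inc.
      - ltd.
      - llc
      - corp.
      - corporation
      - company
      - co.
      - gmbh
      - "s.a."
      - "s.p.a."
      - pharmaceutical
      - pharmaceuticals
      - pharma
      - biopharma
      - therapeutics
      - biosciences
      - biotech
      - laboratories
      - plc
  gov:
    keywords:
      - national institutes
      - national institute
      - national cancer institute
      - ministry
      - "ministère"
      - ministerio
      - government
      - federal
      - veterans affairs
      - national health service
      - centers for disease control
      - food and drug administration
      - county council
      - public health agency
      - army
      - navy
      - air force
  col:
    keywords:
      - association
      - associazione
      - network
      - consortium
      - collaboration
      - collaborative
      - cooperative group
      - alliance
      - society
      - working group
      - federation
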