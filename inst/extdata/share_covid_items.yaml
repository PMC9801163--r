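# Analysis codings and thematic-block membership for the 35 survey items
# behind the nine composite indicators. Codes are the polarity-aligned
# analysis codings: within every block a HIGHER code means a WORSE
# situation since the outbreak. Where an item's raw instrument polarity
# differs, a `recode` map (raw code -> analysis code) can be given;
# the shipped instrument is already aligned, so recodes are identity and
# omitted. `missing_codes` lists codes to be treated as missing.
blocks:
  general_health:
    health_before:            # 1 excellent ... 5 poor
      codes: [1, 2, 3, 4, 5]
    health_change:            # 0 improved / 1 about the same / 2 worsened
      codes: [0, 1, 2]
  physical_health:
    falling_down:             # fell more in last 6 months (0 no / 1 yes)
      codes: [0, 1]
    fear_falling:
      codes: [0, 1]
    dizziness:
      codes: [0, 1]
    fatigue:
      codes: [0, 1]
  mental_health:
    felt_nervous:
      codes: [0, 1]
    sad_depressed:
      codes: [0, 1]
    trouble_sleeping:
      codes: [0, 1]
    feel_lonely:              # 0 hardly ever / 1 some of the time / 2 often
      codes: [0, 1, 2]
  stay_home:
    went_shopping:            # -1 more often / 0 about the same / 1 less often / 2 not any more
      codes: [-1, 0, 1, 2]
    went_walk:
      codes: [-1, 0, 1, 2]
    met_people:               # met >5 people outside the household
      codes: [-1, 0, 1, 2]
    visited_family:
      codes: [-1, 0, 1, 2]
  safety_measures:
    face_mask:                # 0 never / 1 sometimes / 2 often / 3 always
      codes: [0, 1, 2, 3]
    kept_distance:
      codes: [0, 1, 2, 3]
    washed_hands:
      codes: [0, 1]
    hand_sanitizer:
      codes: [0, 1]
    covered_coughs:
      codes: [0, 1]
    covid_drugs:              # took drugs/medicine as prevention
      codes: [0, 1]
  social_contact:
    contact_children:         # 1 daily ... 5 never
      codes: [1, 2, 3, 4, 5]
    contact_relatives:
      codes: [1, 2, 3, 4, 5]
    contact_friends:          # neighbours, friends or colleagues
      codes: [1, 2, 3, 4, 5]
  electronic_social_contact:
    econtact_children:
      codes: [1, 2, 3, 4, 5]
    econtact_relatives:
      codes: [1, 2, 3, 4, 5]
    econtact_friends:
      codes: [1, 2, 3, 4, 5]
  covid:
    covid_symptoms:           # anyone close had symptoms
      codes: [0, 1]
    covid_positive:
      codes: [0, 1]
    covid_hospital:
      codes: [0, 1]
    covid_death:
      codes: [0, 1]
  healthcare:
    forwent_treatment:
      codes: [0, 1]
    postponed_appointment:
      codes: [0, 1]
    denied_appointment:
      codes: [0, 1]
    hospital_treated:         # 0 yes / 1 no (not treated = worse access)
      codes: [0, 1]
    visited_facilities:       # 0 yes / 1 no
      codes: [0, 1]
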