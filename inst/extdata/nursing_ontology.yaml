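# Built-in nursing-care fixture ontology.
# Six action-driven intents; activity slots carry the object of the action
# verb, record slots carry recorded details reached through prepositional
# phrases. Shared record slots (start-time, stop-time, target) are declared
# once and referenced by several intents.
version: "1.0"
slots:
- name: vital-type
  kind: activity
  values: [blood pressure, body temperature, pulse beats]
  synonyms:
    blood pressure: [pressure]
    body temperature: [temperatures]
    pulse beats: [heartbeat]
- name: oral-type
  kind: activity
  values: [mouth, dentures, partial denture, orthodontic braces]
  synonyms:
    dentures: [false teeth]
- name: toilet-type
  kind: activity
  values: [portable toilets, port potty, urinals, waterless urinal]
  synonyms:
    port potty: [porta potty]
- name: food-type
  kind: activity
  values: [noodles, tofu, vegetable soup, chicken soup, fruits]
  synonyms:
    noodles: [udon]
- name: bath-type
  kind: activity
  values: [baths, shower, wipe]
  synonyms:
    baths: [bathtub]
- name: diaper-type
  kind: activity
  values: [dirty diaper, soiled diaper, nappies, wet diaper]
- name: vital-value
  kind: record
  values: [mmHg, systolic BP, c, celcius, bpm, heartrate]
- name: oral-material
  kind: record
  values: [interdental brushes, dental floss, detergent, water]
  synonyms:
    detergent: [dishwashing liquid]
    water: [freshwater]
- name: toilet-place
  kind: record
  values: [toilets, lavatory, restroom, bathroom, loo]
  synonyms:
    bathroom: [washroom]
- name: meal-type
  kind: record
  values: [breakfasts, lunch, brunch, dinner, meal, supper]
- name: bath-material
  kind: record
  values: [lift, steal, bar stool, worktable, swivel chair]
- name: start-time
  kind: record
  values: [9 am, 8:30 am, half past six, noon, 10:30 pm]
- name: stop-time
  kind: record
  values: [9:30 am, 10 am, 8 pm, 11 o clock, midday]
- name: target
  kind: record
  values: [patient a, patient b, patient c, room 303, a group of patients]
intents:
- name: add-vital
  verbs: [add, set, put, record]
  activity_slot: vital-type
  record_templates:
  - preposition: with
    modifiers: ['103', '39', '80', '114', '88', '155']
    slot: vital-value
    pattern: 2
  - preposition: to
    slot: target
    pattern: 1
- name: clean-oral
  verbs: [clean, wash, brush]
  activity_slot: oral-type
  record_templates:
  - preposition: with
    slot: oral-material
    pattern: 1
  - preposition: for
    slot: target
    pattern: 1
- name: assist-toilet
  verbs: [help to use, assist to use]
  activity_slot: toilet-type
  record_templates:
  - preposition: at
    slot: toilet-place
    pattern: 1
  - preposition: from
    slot: start-time
    pattern: 1
- name: prepare-meal
  verbs: [prepare, make, cook]
  activity_slot: food-type
  record_templates:
  - preposition: for
    slot: meal-type
    pattern: 1
  - preposition: at
    slot: start-time
    pattern: 1
- name: assist-bath
  verbs: [help to, assist to]
  activity_slot: bath-type
  record_templates:
  - preposition: with
    slot: bath-material
    pattern: 1
  - preposition: until
    slot: stop-time
    pattern: 1
- name: change-diaper
  verbs: [change, replace]
  activity_slot: diaper-type
  record_templates:
  - preposition: at
    slot: toilet-place
    pattern: 1
  - preposition: for
    slot: target
    pattern: 1
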