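[
  {"name": "exercise",          "label": "Engage in exercise",        "is_health": true,  "is_risk": false},
  {"name": "smoking",           "label": "Avoid smoking",             "is_health": true,  "is_risk": true},
  {"name": "getting_drunk",     "label": "Avoid getting drunk",       "is_health": true,  "is_risk": true},
  {"name": "eat_fruit",         "label": "Eat fruit",                 "is_health": true,  "is_risk": false},
  {"name": "fast_food",         "label": "Avoid fast food",           "is_health": true,  "is_risk": true},
  {"name": "buy_magazine",      "label": "Buy a magazine",            "is_health": false, "is_risk": false},
  {"name": "buy_newspaper",     "label": "Buy a newspaper",           "is_health": false, "is_risk": false},
  {"name": "read_pleasure",     "label": "Read for pleasure",         "is_health": false, "is_risk": false},
  {"name": "vitamin_pills",     "label": "Take vitamin pills",        "is_health": false, "is_risk": false},
  {"name": "visit_friend",      "label": "Visit a friend",            "is_health": false, "is_risk": false},
  {"name": "meal_out",          "label": "Go out for a meal",         "is_health": false, "is_risk": false},
  {"name": "attend_lectures",   "label": "Attend all lectures",       "is_health": false, "is_risk": false},
  {"name": "sleep_7hours",      "label": "7 hours sleep",             "is_health": false, "is_risk": false},
  {"name": "buy_clothes",       "label": "Buy clothes",               "is_health": false, "is_risk": false},
  {"name": "no_lie_in",         "label": "Not lying-in past 9.00am",  "is_health": false, "is_risk": false},
  {"name": "cinema",            "label": "Go to cinema",              "is_health": false, "is_risk": false},
  {"name": "walk",              "label": "Go for a walk",             "is_health": false, "is_risk": false},
  {"name": "independent_study", "label": "Independent study",         "is_health": false, "is_risk": false},
  {"name": "write_letter",      "label": "Write a letter",            "is_health": false, "is_risk": false},
  {"name": "recycle_bottles",   "label": "Recycle bottles",           "is_health": false, "is_risk": false},
  {"name": "countryside",       "label": "Visit the countryside",     "is_health": false, "is_risk": false},
  {"name": "library",           "label": "Go to the library",         "is_health": false, "is_risk": false},
  {"name": "avoid_meat",        "label": "Avoid eating meat",         "is_health": false, "is_risk": false},
  {"name": "rent_video",        "label": "Rent a video",              "is_health": false, "is_risk": false},
  {"name": "shopping",          "label": "Go shopping",               "is_health": false, "is_risk": false},
  {"name": "visit_parents",     "label": "Visit parents",             "is_health": false, "is_risk": false},
  {"name": "clubbing",          "label": "Go clubbing",               "is_health": false, "is_risk": false},
  {"name": "tidy_room",         "label": "Tidy room",                 "is_health": false, "is_risk": false}
]
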