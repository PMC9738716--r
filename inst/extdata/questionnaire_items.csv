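"item","factor","prompt"
"Q1-1","reward","Does it taste like a habit?"
"Q1-2","reward","Does it taste like something you would want to pick up?"
"Q1-3","reward","Does one bite make you want to take another bite?"
"Q1-4","reward","Are you satisfied with the taste?"
"Q1-5","reward","Do you think that the food tastes good because of its fatty sweetness and delicious taste?"
"Q2-1","cultural","Does it taste familiar to you?"
"Q2-2","cultural","Have you ever eaten food that tasted the same or similar to you?"
"Q2-3","cultural","Have you eaten food like this many times?"
"Q2-4","cultural","Do you think your family will like the taste of this food?"
"Q2-5","cultural","Did you like the taste since you were a child?"
"Q3-1","information","Does the food look good to you?"
"Q3-2","information","Have you seen this food in advertisements or heard about it by word of mouth?"
"Q3-3","information","Have you ever heard of the health benefits?"
"Q3-4","information","Do you feel comfortable with the ingredients?"
"Q3-5","information","Do you think it looks expensive?"
"Q4-1","appearance","Is the size of this food desirable?"
"Q4-2","appearance","Does it look colorful and delicious?"
"Q4-3","appearance","Does it look shiny and delicious?"
"Q4-4","appearance","Do you think it smells good?"
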