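meal_label,half_time_min,kcal,viscosity_class,method
500 mL 0.25 g/100 g LBG (0.01 Pa s),17,NA,low,epmri
500 mL 0.5 g/100 g LBG (0.1 Pa s),18,NA,low,epmri
500 mL 1.0 g/100 g LBG (2 Pa s),18,NA,high,epmri
500 mL 1.5 g/100 g LBG (11 Pa s),19,NA,high,epmri
500 mL 64 kcal LV,32,64,low,epmri
500 mL 64 kcal HV,46,64,high,epmri
500 mL 322.65 kcal LV,67,322.65,low,epmri
500 mL 322.65 kcal HV,79,322.65,high,epmri
600 mL 96 kcal glucose LV,17,96,low,aspiration
600 mL 96 kcal glucose HV,14,96,high,aspiration
600 mL 451 kcal glucose LV,130,451,low,aspiration
600 mL 451 kcal glucose HV,64,451,high,aspiration
600 mL 60 kcal glucose,9.4,60,low,aspiration
600 mL 132 kcal PPH,16.3,132,low,aspiration
600 mL 138 kcal WPH,17.2,138,low,aspiration
600 mL 396 kcal MP,26.4,396,low,aspiration
300 mL 400 kcal glucose,107,400,low,scintigraphy
450 mL 200 kcal glucose,66,200,low,scintigraphy
500 mL 500 kcal mixed LV,72.1,500,low,ultrasonography
500 mL 500 kcal mixed HV,85.5,500,high,ultrasonography
400 mL 400 kcal mixed LV,257.9,400,low,breath_13C
400 mL 400 kcal mixed HV,195.1,400,high,breath_13C
400 mL water,99.4,0,low,breath_13C
240 kcal solid/liquid meal,77,240,solid,epmri
240 kcal soup,92,240,low,epmri
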