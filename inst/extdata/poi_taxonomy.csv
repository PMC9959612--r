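category,subcategory,count
commercial,catering_service,54304
commercial,shopping_service,92448
commercial,accommodation_service,12364
commercial,living_service,68669
commercial,leisure_entertainment,3343
residential,business_residence,9250
public_service,medical_care,14439
public_service,education_culture,17474
public_service,government_agencies,15507
public_service,athletic_sports,4019
traffic,transportation_facilities,21379
green_space,scenic_spots,2007
industrial,companies,37940
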