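# Food taxonomy: 9 categories, 30 base sub-categories.
# The fruits, milk and yogurts sub-categories are split further
# (fresh/processed, plain/sweet) to separate intrinsic from free sugars,
# giving 33 leaf sub-categories. Foods are labelled at the leaf level.
# "beverage: true" marks leaves typically consumed as beverages (excluded
# from solid energy density; milk and juices count as beverages, soups as
# solid food).
categories:
  - name: "Fruits/vegetables/nuts"
    subcategories:
      - {name: "Fresh fruits", base: "Fruits"}
      - {name: "Processed fruits", base: "Fruits"}
      - {name: "Vegetables"}
      - {name: "Soups"}
      - {name: "Nuts"}
  - name: "Starchy foods"
    subcategories:
      - {name: "Refined starchy foods"}
      - {name: "Unrefined starchy foods"}
      - {name: "Ready-to-eat cereals"}
  - name: "Meats/eggs/fish"
    subcategories:
      - {name: "Meats"}
      - {name: "Eggs"}
      - {name: "Fish"}
  - name: "Mixed dishes and sandwiches"
    subcategories:
      - {name: "Mixed dishes"}
      - {name: "Sandwiches"}
  - name: "Dairy products"
    subcategories:
      - {name: "Plain milk", base: "Milk", beverage: true}
      - {name: "Sweet milk", base: "Milk", beverage: true}
      - {name: "Plain yogurts", base: "Yogurts"}
      - {name: "Sweet yogurts", base: "Yogurts"}
      - {name: "Cheese"}
  - name: "Sweet products"
    subcategories:
      - {name: "Milk or eggs-containing desserts"}
      - {name: "Cakes and pastries"}
      - {name: "Biscuits"}
      - {name: "Croissants"}
      - {name: "Confectionery"}
      - {name: "Honey, marmalade and chocolate spread"}
      - {name: "Table sugar"}
  - name: "Beverages including water"
    subcategories:
      - {name: "Water", beverage: true}
      - {name: "Hot beverages", beverage: true}
      - {name: "Diet beverages", beverage: true}
      - {name: "Sugar-sweetened beverages", beverage: true}
      - {name: "Fruit juices", beverage: true}
  - name: "Added fats and sauces"
    subcategories:
      - {name: "Added fats"}
      - {name: "Sauces"}
  - name: "Foods based on soya"
    subcategories:
      - {name: "Soya products"}
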